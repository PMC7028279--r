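# Scenario S5: Disrupted DS plans with ToM, moderate disruption, delta = 0.5
scenario: S5
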