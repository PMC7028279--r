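# Scenario S2: Disrupted DS plans with ToM, short disruption, delta = 0.5
scenario: S2
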