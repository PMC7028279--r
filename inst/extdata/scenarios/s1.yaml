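# Scenario S1: no Theory-of-Mind planning, short disruption, delta = 0.5
scenario: S1
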