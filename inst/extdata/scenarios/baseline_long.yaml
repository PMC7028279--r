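# Comparison baseline for S4: both healthcenters split orders equally
scenario: S4
split_rules:
  Trust HC: equal
  Equal HC: equal
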