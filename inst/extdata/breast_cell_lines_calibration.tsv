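survival_pct	entropy
70	11.4332400
90	11.4294941
100	11.4150921
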