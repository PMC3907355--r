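population	n_controls
CEU	34
ASI	8
MXL	4
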