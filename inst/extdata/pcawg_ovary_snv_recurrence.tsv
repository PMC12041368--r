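k	n_positions
9	1
4	2
3	7
2	475
1	980687
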