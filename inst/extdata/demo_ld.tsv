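marker_a	marker_b	r
m1	m2	0.8
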