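study	SET1	SET2
s1	0.02	0.55
s2	0.04	0.4
s3	0.01	0.7
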