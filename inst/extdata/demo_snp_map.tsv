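marker	gene
m1	gA
m2	gA
m3	gB
m4	gC
m5	gD
m6	gE
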