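SET1	transporter demo set	gA	gB	gC
SET2	receptor demo set	gC	gD	gE
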