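study	marker	gene	theta	se	p
s1	m1	gA	0.2957	0.12	0.0137332
s1	m2	gA	0.2676	0.12	0.0257474
s1	m3	gB	0.2505	0.12	0.036843
s1	m4	gC	0.0533	0.12	0.656922
s1	m5	gD	-0.0435	0.12	0.716978
s1	m6	gE	0.0147	0.12	0.902503
s2	m1	gA	0.1663	0.12	0.165798
s2	m2	gA	0.2688	0.12	0.0250909
s2	m3	gB	0.1963	0.12	0.101874
s2	m4	gC	-0.1553	0.12	0.195608
s2	m5	gD	-0.0895	0.12	0.455768
s2	m6	gE	0.1106	0.12	0.356702
s3	m1	gA	0.36	0.12	0.0026998
s3	m2	gA	-0.091	0.12	0.448251
s3	m3	gB	-0.1249	0.12	0.297953
s3	m4	gC	0	0.12	1
s3	m5	gD	-0.0473	0.12	0.693458
s3	m6	gE	-0.2094	0.12	0.0809849
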