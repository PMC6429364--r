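mtbd	segment	n_contacts	percentage_printed
cytoplasmic	LH1	401	70.97
cytoplasmic	H1	5	0.88
cytoplasmic	H2	0	0.00
cytoplasmic	H3	0	0.00
cytoplasmic	H4	0	0.00
cytoplasmic	H5	159	28.14
cytoplasmic	H6	0	0.00
axonemal	LH1	95	0.82
axonemal	H1	0	0.00
axonemal	H2	1871	16.10
axonemal	H3	0	0.00
axonemal	H4	0	0.00
axonemal	H5	1081	9.30
axonemal	H6	0	0.00
axonemal	FLAP	4780	41.11
axonemal	LF	3799	32.67
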