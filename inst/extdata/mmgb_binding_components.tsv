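system	with_tails	e_complex	e_mtbd	e_mt	de_printed	sd_printed
cytoplasmic	yes	-22243.6	-3906.06	-18296.7	-40.84	7.56
cytoplasmic	no	-20113.2	-3906.06	-16227.9	20.76	6.71
axonemal	yes	-21851.2	-3520.25	-18302.2	-28.75	6.33
axonemal	no	-19726	-3520.25	-16230.8	25.05	10.29
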