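block	free_cluster	free_pop	bound_cluster	bound_pop	rmsd
cyto_0	1	59.8	1	51.2	5
cyto_0	1	59.8	2	20.85	5.2
cyto_0	1	59.8	3	8.6	5.17
cyto_0	1	59.8	4	7.95	4.79
cyto_0	1	59.8	5	4.45	5.86
cyto_0	2	8.1	1	51.2	3.83
cyto_0	2	8.1	2	20.85	3.56
cyto_0	2	8.1	3	8.6	3.58
cyto_0	2	8.1	4	7.95	3.33
cyto_0	2	8.1	5	4.45	4.1
cyto_0	3	6.5	1	51.2	3.32
cyto_0	3	6.5	2	20.85	3.27
cyto_0	3	6.5	3	8.6	3.21
cyto_0	3	6.5	4	7.95	4.08
cyto_0	3	6.5	5	4.45	5.39
cyto_0	4	5.3	1	51.2	2.9
cyto_0	4	5.3	2	20.85	3
cyto_0	4	5.3	3	8.6	3.03
cyto_0	4	5.3	4	7.95	3.5
cyto_0	4	5.3	5	4.45	5.57
cyto_0	5	4.7	1	51.2	2.68
cyto_0	5	4.7	2	20.85	2.28
cyto_0	5	4.7	3	8.6	2.31
cyto_0	5	4.7	4	7.95	3.06
cyto_0	5	4.7	5	4.45	4.3
cyto_25	1	59.8	1	33	7.04
cyto_25	1	59.8	2	19.1	4.91
cyto_25	1	59.8	3	12.65	6.31
cyto_25	1	59.8	4	9.32	6.35
cyto_25	1	59.8	5	5.05	5.82
cyto_25	2	8.1	1	33	6.67
cyto_25	2	8.1	2	19.1	3.28
cyto_25	2	8.1	3	12.65	4.66
cyto_25	2	8.1	4	9.32	5.68
cyto_25	2	8.1	5	5.05	5.94
cyto_25	3	6.5	1	33	6.35
cyto_25	3	6.5	2	19.1	3.37
cyto_25	3	6.5	3	12.65	5.98
cyto_25	3	6.5	4	9.32	6.29
cyto_25	3	6.5	5	5.05	6.36
cyto_25	4	5.3	1	33	6.37
cyto_25	4	5.3	2	19.1	2.87
cyto_25	4	5.3	3	12.65	5.5
cyto_25	4	5.3	4	9.32	5.94
cyto_25	4	5.3	5	5.05	6.01
cyto_25	5	4.7	1	33	5.63
cyto_25	5	4.7	2	19.1	2.8
cyto_25	5	4.7	3	12.65	5.29
cyto_25	5	4.7	4	9.32	5.65
cyto_25	5	4.7	5	5.05	5.9
axo_0	1	59.8	1	31.54	4.35
axo_0	1	59.8	2	16.12	5.83
axo_0	1	59.8	3	7.44	5.58
axo_0	1	59.8	4	4.94	4.51
axo_0	1	59.8	5	4.24	5.39
axo_0	2	8.1	1	31.54	3.25
axo_0	2	8.1	2	16.12	3.96
axo_0	2	8.1	3	7.44	4.62
axo_0	2	8.1	4	4.94	4.99
axo_0	2	8.1	5	4.24	4.28
axo_0	3	6.5	1	31.54	2.88
axo_0	3	6.5	2	16.12	4.08
axo_0	3	6.5	3	7.44	5.69
axo_0	3	6.5	4	4.94	3.88
axo_0	3	6.5	5	4.24	5.17
axo_0	4	5.3	1	31.54	2.24
axo_0	4	5.3	2	16.12	3.89
axo_0	4	5.3	3	7.44	4.92
axo_0	4	5.3	4	4.94	3.14
axo_0	4	5.3	5	4.24	4.69
axo_0	5	4.7	1	31.54	3.47
axo_0	5	4.7	2	16.12	4.28
axo_0	5	4.7	3	7.44	5.53
axo_0	5	4.7	4	4.94	4.72
axo_0	5	4.7	5	4.24	4.9
axo_25	1	59.8	1	36.15	5.01
axo_25	1	59.8	2	27.3	4.98
axo_25	1	59.8	3	16.35	5.18
axo_25	1	59.8	4	6.65	4.87
axo_25	1	59.8	5	4.8	4.73
axo_25	2	8.1	1	36.15	3.6
axo_25	2	8.1	2	27.3	3.84
axo_25	2	8.1	3	16.35	4.25
axo_25	2	8.1	4	6.65	3.5
axo_25	2	8.1	5	4.8	3.57
axo_25	3	6.5	1	36.15	2.21
axo_25	3	6.5	2	27.3	3.42
axo_25	3	6.5	3	16.35	2.95
axo_25	3	6.5	4	6.65	2.72
axo_25	3	6.5	5	4.8	2.67
axo_25	4	5.3	1	36.15	2.2
axo_25	4	5.3	2	27.3	2.87
axo_25	4	5.3	3	16.35	2.66
axo_25	4	5.3	4	6.65	2.37
axo_25	4	5.3	5	4.8	2.15
axo_25	5	4.7	1	36.15	3.18
axo_25	5	4.7	2	27.3	2.97
axo_25	5	4.7	3	16.35	3.62
axo_25	5	4.7	4	6.65	2.86
axo_25	5	4.7	5	4.8	3.35
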