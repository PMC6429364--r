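mtbd	ehook	resname	resno	distance	n_contacts
cytoplasmic	B	LYS	3295	0	16
cytoplasmic	B	LYS	3295	5	7
cytoplasmic	B	LYS	3295	15	1
cytoplasmic	B	LYS	3295	25	0
cytoplasmic	B	LYS	3295	35	0
cytoplasmic	B	SER	3296	0	16
cytoplasmic	B	SER	3296	5	0
cytoplasmic	B	SER	3296	15	1
cytoplasmic	B	SER	3296	25	0
cytoplasmic	B	SER	3296	35	0
cytoplasmic	B	ILE	3297	0	6
cytoplasmic	B	ILE	3297	5	0
cytoplasmic	B	ILE	3297	15	0
cytoplasmic	B	ILE	3297	25	0
cytoplasmic	B	ILE	3297	35	0
cytoplasmic	B	LYS	3298	0	363
cytoplasmic	B	LYS	3298	5	505
cytoplasmic	B	LYS	3298	15	334
cytoplasmic	B	LYS	3298	25	97
cytoplasmic	B	LYS	3298	35	4
cytoplasmic	B	LYS	3299	0	4
cytoplasmic	B	LYS	3299	5	0
cytoplasmic	B	LYS	3299	15	30
cytoplasmic	B	LYS	3299	25	162
cytoplasmic	B	LYS	3299	35	14
cytoplasmic	B	GLN	3300	0	1
cytoplasmic	B	GLN	3300	5	0
cytoplasmic	B	GLN	3300	15	58
cytoplasmic	B	GLN	3300	25	68
cytoplasmic	B	GLN	3300	35	2
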