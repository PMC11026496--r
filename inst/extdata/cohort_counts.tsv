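cohort	class	total	matched	faithful
tissue	MB	61	61	NA
tissue	LGG	45	43	NA
tissue	HGG	23	23	NA
tissue	DMG	13	13	NA
tissue	EPN	9	9	NA
tissue	MNG	4	4	NA
cell	MB	21	15	5
cell	LGG	22	3	3
cell	HGG	17	5	3
cell	DMG	24	16	10
cell	EPN	2	2	NA
cell	MNG	0	0	NA
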