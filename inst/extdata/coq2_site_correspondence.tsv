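homolog_aa	homolog_pos	query_aa	query_pos	role
R	43	R	123	phb_carboxyl
N	50	N	130	tail_c1
D	54	D	134	ppi_mg
D	58	D	138	ppi_mg
R	63	R	143	ppi_mg
R	67	R	147	ppi_mg
Y	115	Y	195	ppi_mg
K	119	K	199	ppi_mg
D	175	D	248	tail_c1
Y	178	Y	251	tail_c1
D	182	D	255	ppi_mg
D	186	D	259	ppi_mg
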