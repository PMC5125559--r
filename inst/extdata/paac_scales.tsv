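scale	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
hydrophobicity	0.62	-2.53	-0.78	-0.90	0.29	-0.85	-0.74	0.48	-0.40	1.38	1.06	-1.50	0.64	1.19	0.12	-0.18	-0.05	0.81	0.26	1.08
hydrophilicity	-0.5	3.0	0.2	3.0	-1.0	0.2	3.0	0.0	-0.5	-1.8	-1.8	3.0	-1.3	-2.5	0.0	0.3	-0.4	-3.4	-2.3	-1.5
side_chain_mass	15.0	101.0	58.0	59.0	47.0	72.0	73.0	1.0	82.0	57.0	57.0	73.0	75.0	91.0	42.0	31.0	45.0	130.0	107.0	43.0
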