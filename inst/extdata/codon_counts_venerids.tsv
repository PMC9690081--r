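codon	aa	count_Rphilippinarum	rscu_Rphilippinarum	count_Rvariegatus	rscu_Rvariegatus
UUU	F	430	1.74	324	1.68
UUC	F	63	0.26	61	0.32
UUA	L	430	3.59	265	3.04
UUG	L	116	0.97	139	1.59
CUU	L	104	0.87	39	0.45
CUC	L	2	0.02	7	0.08
CUA	L	55	0.46	43	0.49
CUG	L	12	0.10	30	0.34
AUU	I	239	1.38	174	1.49
AUC	I	29	0.17	25	0.21
AUA	M	253	1.46	151	1.29
AUG	M	79	1.00	98	1.00
GUU	V	238	1.84	154	1.42
GUC	V	25	0.19	20	0.18
GUA	V	195	1.51	134	1.23
GUG	V	59	0.46	127	1.17
UCU	S	141	2.50	68	1.81
UCC	S	12	0.21	10	0.27
UCA	S	46	0.81	34	0.91
UCG	S	12	0.21	32	0.85
CCU	P	82	2.25	66	2.13
CCC	P	11	0.30	8	0.26
CCA	P	42	1.15	35	1.13
CCG	P	11	0.30	15	0.48
ACU	T	104	2.52	57	1.93
ACC	T	6	0.15	7	0.24
ACA	T	44	1.07	30	1.02
ACG	T	11	0.27	24	0.81
GCU	A	129	2.73	103	2.11
GCC	A	11	0.23	19	0.39
GCA	A	40	0.85	36	0.74
GCG	A	9	0.19	37	0.76
UAU	Y	171	1.65	140	1.56
UAC	Y	36	0.35	40	0.44
CAU	H	73	1.83	46	1.48
CAC	H	7	0.17	16	0.52
CAA	Q	38	1.27	38	1.25
CAG	Q	22	0.73	23	0.75
AAU	N	153	1.72	72	1.45
AAC	N	25	0.28	27	0.55
AAA	K	138	1.45	71	1.06
AAG	K	53	0.55	63	0.94
GAU	D	99	1.61	77	1.62
GAC	D	24	0.39	18	0.38
GAA	E	91	0.98	66	0.94
GAG	E	95	1.02	74	1.06
UGU	C	105	1.74	88	1.60
UGC	C	16	0.26	22	0.40
UGA	W	65	3.00	39	3.00
UGG	W	72	1.00	65	1.00
CGU	R	35	0.65	30	0.62
CGC	R	0	0.00	3	0.06
CGA	R	30	0.55	18	0.37
CGG	R	14	0.26	29	0.60
AGU	S	112	1.98	62	1.65
AGC	S	16	0.28	19	0.51
AGA	R	154	2.84	90	1.86
AGG	R	92	1.70	121	2.49
GGU	G	180	1.74	98	1.11
GGC	G	12	0.12	17	0.19
GGA	G	90	0.87	88	1.00
GGG	G	131	1.27	149	1.69
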