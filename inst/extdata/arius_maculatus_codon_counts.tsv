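amino_acid	codon	count	frequency_pct	rscu
Ala	GCC	161	4.24	1.92
Ala	GCA	100	2.63	1.19
Ala	GCT	67	1.76	0.80
Ala	GCG	8	0.21	0.10
Arg	CGA	39	1.03	2.14
Arg	CGC	16	0.42	0.88
Arg	CGG	11	0.29	0.60
Arg	CGT	7	0.18	0.38
Asn	AAC	79	2.08	1.26
Asn	AAT	46	1.21	0.74
Asp	GAC	53	1.39	1.36
Asp	GAT	25	0.66	0.64
Cys	TGC	15	0.39	1.11
Cys	TGT	12	0.32	0.89
Gln	CAA	86	2.26	1.76
Gln	CAG	12	0.32	0.24
Glu	GAA	83	2.18	1.69
Glu	GAG	15	0.39	0.31
Gly	GGA	102	2.68	1.69
Gly	GGC	88	2.32	1.46
Gly	GGG	27	0.71	0.45
Gly	GGT	24	0.63	0.40
His	CAC	84	2.21	1.57
His	CAT	23	0.61	0.43
Ile	ATC	156	4.10	1.02
Ile	ATT	151	3.97	0.98
Leu	CTA	274	7.21	2.53
Leu	CTC	138	3.63	1.27
Leu	TTA	102	2.68	0.94
Leu	CTT	78	2.05	0.72
Leu	CTG	41	1.08	0.38
Leu	TTG	17	0.45	0.16
Lys	AAA	75	1.97	1.92
Lys	AAG	3	0.08	0.08
Met	ATA	120	3.16	1.45
Met	ATG	46	1.21	0.55
Phe	TTC	130	3.42	1.16
Phe	TTT	94	2.47	0.84
Pro	CCC	90	2.37	1.65
Pro	CCA	86	2.26	1.58
Pro	CCT	38	1.00	0.70
Pro	CCG	4	0.11	0.07
Ser	TCC	86	2.26	2.22
Ser	TCA	70	1.84	1.81
Ser	AGC	38	1.00	0.98
Ser	TCT	27	0.71	0.70
Ser	AGT	6	0.16	0.16
Ser	TCG	5	0.13	0.13
Stp	TAA	6	0.16	2.67
Stp	TAG	3	0.08	1.33
Stp	AGA	0	0.00	0.00
Stp	AGG	0	0.00	0.00
Thr	ACC	121	3.18	1.66
Thr	ACA	113	2.97	1.55
Thr	ACT	54	1.42	0.74
Thr	ACG	4	0.11	0.05
Trp	TGA	99	2.60	1.62
Trp	TGG	23	0.61	0.38
Tyr	TAC	72	1.89	1.26
Tyr	TAT	42	1.10	0.74
Val	GTA	77	2.03	1.50
Val	GTT	55	1.45	1.07
Val	GTC	51	1.34	0.99
Val	GTG	23	0.61	0.45
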