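name	type	from	to	size	strand	n_aa	anticodon	init_codon	term_codon	intergenic
tRNA-Phe	tRNA	1	70	70	H	NA	GAA	NA	NA	0
12S-rRNA	rRNA	71	1028	958	H	NA	NA	NA	NA	0
tRNA-Val	tRNA	1029	1100	72	H	NA	TAC	NA	NA	0
16S-rRNA	rRNA	1101	2775	1675	H	NA	NA	NA	NA	0
tRNA-Leu	tRNA	2776	2850	75	H	NA	TAA	NA	NA	1
ND1	PCG	2852	3826	975	H	324	NA	ATG	TAA	1
tRNA-Ile	tRNA	3828	3899	72	H	NA	GAT	NA	NA	-1
tRNA-Gln	tRNA	3899	3969	71	L	NA	TTG	NA	NA	-1
tRNA-Met	tRNA	3969	4038	70	H	NA	CAT	NA	NA	0
ND2	PCG	4039	5085	1047	H	348	NA	ATG	TAG	-2
tRNA-Trp	tRNA	5084	5154	71	H	NA	TCA	NA	NA	2
tRNA-Ala	tRNA	5157	5225	69	L	NA	TGC	NA	NA	1
tRNA-Asn	tRNA	5227	5299	73	L	NA	GTT	NA	NA	31
tRNA-Cys	tRNA	5331	5396	66	L	NA	GCA	NA	NA	1
tRNA-Tyr	tRNA	5398	5467	70	L	NA	GTA	NA	NA	1
COXI	PCG	5469	7019	1551	H	516	NA	GTG	TAA	0
tRNA-Ser	tRNA	7020	7090	71	L	NA	TGA	NA	NA	4
tRNA-Asp	tRNA	7095	7163	69	H	NA	GTC	NA	NA	14
COXII	PCG	7178	7868	691	H	230	NA	ATG	T	0
tRNA-Lys	tRNA	7869	7942	74	H	NA	TTT	NA	NA	1
ATP8	PCG	7944	8111	168	H	55	NA	ATG	TAA	-10
ATP6	PCG	8102	8785	684	H	227	NA	ATG	TAA	-1
COXIII	PCG	8785	9568	784	H	261	NA	ATG	T	0
tRNA-Gly	tRNA	9569	9641	73	H	NA	TCC	NA	NA	0
ND3	PCG	9642	9992	351	H	116	NA	ATG	TAG	-2
tRNA-Arg	tRNA	9991	10061	71	H	NA	TCG	NA	NA	0
ND4L	PCG	10062	10358	297	H	98	NA	ATG	TAA	-7
ND4	PCG	10352	11732	1381	H	460	NA	ATG	T	0
tRNA-His	tRNA	11733	11802	70	H	NA	GTG	NA	NA	0
tRNA-Ser	tRNA	11803	11869	67	H	NA	GCT	NA	NA	8
tRNA-Leu	tRNA	11878	11950	73	H	NA	TAG	NA	NA	0
ND5	PCG	11951	13777	1827	H	608	NA	ATG	TAA	-4
ND6	PCG	13774	14286	513	L	170	NA	ATG	TAG	0
tRNA-Glu	tRNA	14287	14355	69	L	NA	TTC	NA	NA	1
Cytb	PCG	14357	15494	1138	H	379	NA	ATG	T	0
tRNA-Thr	tRNA	15495	15566	72	H	NA	TGT	NA	NA	-2
tRNA-Pro	tRNA	15565	15634	70	L	NA	TGG	NA	NA	0
D-loop	control_region	15635	16710	1076	H	NA	NA	NA	NA	0
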