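amino_acid	codon	count	rscu_published
Phe	UUU	240	1.57
Phe	UUC	65	0.43
Leu	UUA	74	0.59
Leu	UUG	225	1.80
Leu	CUU	84	0.67
Leu	CUC	112	0.90
Leu	CUA	71	0.57
Leu	CUG	183	1.47
Ile	AUU	336	1.65
Ile	AUC	181	0.89
Ile	AUA	95	0.47
Val	GUU	89	0.64
Val	GUC	95	0.68
Val	GUA	95	0.68
Val	GUG	278	2.00
Ser	AGU	73	0.69
Ser	AGC	206	1.94
Ser	UCU	64	0.60
Ser	UCC	81	0.76
Ser	UCA	42	0.39
Ser	UCG	172	1.62
Pro	CCU	32	0.54
Pro	CCC	74	1.26
Pro	CCA	22	0.37
Pro	CCG	107	1.82
Thr	ACU	103	0.68
Thr	ACC	208	1.37
Thr	ACA	94	0.62
Thr	ACG	204	1.34
Ala	GCU	72	0.68
Ala	GCC	168	1.59
Ala	GCA	28	0.27
Ala	GCG	154	1.46
Tyr	UAU	84	0.59
Tyr	UAC	202	1.41
His	CAU	93	0.63
His	CAC	203	1.37
Gln	CAA	141	1.11
Gln	CAG	114	0.89
Asn	AAU	182	0.51
Asn	AAC	528	1.49
Lys	AAA	367	1.19
Lys	AAG	248	0.81
Asp	GAU	149	0.46
Asp	GAC	497	1.54
Glu	GAA	286	0.97
Glu	GAG	306	1.03
Cys	UGU	77	0.56
Cys	UGC	200	1.44
Arg	CGU	73	1.01
Arg	CGC	196	2.72
Arg	CGA	39	0.54
Arg	CGG	52	0.72
Arg	AGA	41	0.57
Arg	AGG	32	0.44
Gly	GGU	79	0.67
Gly	GGC	321	2.72
Gly	GGA	44	0.37
Gly	GGG	28	0.24
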