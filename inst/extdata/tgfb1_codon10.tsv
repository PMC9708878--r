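study_id	polymorphism	disease	n_case	n_control	case_aa	case_ab	case_bb	ctrl_aa	ctrl_ab	ctrl_bb	allele_common	allele_variant	hwe_case	hwe_control
Basturk 2008	codon 10	CHB	27	60	2	20	5	16	31	13	Leu	Pro	0.009	0.781
Dondeti 2017	codon 10	CHB	115	119	44	70	1	40	70	9	Leu	Pro	0.000	0.004
Eskandari 2017	codon 10	CHB	196	198	23	118	55	46	103	49	Leu	Pro	0.001	0.567
Fabricio-Silva 2015	codon 10	CHC	245	189	70	117	58	54	103	32	Leu	Pro	0.505	0.149
Falleti 2008	codon 10	Cirrhosis	188	140	51	95	42	49	62	29	Leu	Pro	0.859	0.257
Lee 2011	codon 10	Cirrhosis	182	119	61	79	42	35	53	31	Leu	Pro	0.099	0.238
Obada 2017	codon 10	CHC	150	100	42	78	30	32	47	21	Leu	Pro	0.567	0.628
Oliver 2005	codon 10	ALD	165	185	72	68	25	75	77	33	Leu	Pro	0.186	0.096
Paladino 2010	codon 10	AIH	178	189	46	65	67	55	95	39	Leu	Pro	0.001	0.863
Pereira 2008	codon 10	CHC	128	94	26	65	37	24	49	21	Leu	Pro	0.793	0.672
Romani 2011	codon 10	CHC	164	169	50	81	33	49	85	35	Leu	Pro	0.985	0.867
Suzuki 2003	codon 10	CHC	206	101	56	84	66	28	52	21	Leu	Pro	0.009	0.727
Talaat 2013	codon 10	CHB	65	27	10	44	11	0	15	12	Leu	Pro	0.004	0.046
Vidigal 2002	codon 10	CHC	80	37	29	38	13	12	21	4	Leu	Pro	0.926	0.246
Wang 2008	codon 10	Cirrhosis	118	104	34	53	31	25	50	29	Leu	Pro	0.272	0.706
Yousefi 2019	codon 10	AIH	44	138	6	7	31	27	91	20	Leu	Pro	0.000	0.000
Zein 2004 Caucasian	codon 10	CHC	31	36	10	4	17	12	3	21	Leu	Pro	0.000	0.000
Zein 2004 Egyptian	codon 10	CHC	24	45	6	3	15	12	11	22	Leu	Pro	0.001	0.001
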