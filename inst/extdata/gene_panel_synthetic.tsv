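chromosome	start_bp	end_bp	gene	category
1	6000000	8500000	RSU1	ATO
3	6000000	8500000	TTC6	ATO
5	6000000	8500000	TSHR	ATO
7	6000000	8500000	ACSL1	ATO
9	6000000	8500000	TH	BM
11	6000000	8500000	COMT	BM
13	6000000	8500000	SEZ6L	BM
15	6000000	8500000	GTF2I	BM
17	6000000	8500000	GTF2IRD1	BM
19	6000000	8500000	TXNRD2	BM
21	6000000	8500000	OXTR	BM
23	6000000	8500000	DRD4	BM
25	6000000	8500000	SLC6A4	BM
27	6000000	8500000	MAOA	BM
29	6000000	8500000	AR	BM
31	6000000	8500000	MLPH	CC
33	6000000	8500000	MITF	CC
35	6000000	8500000	AP3B1	CC
37	6000000	8500000	PMEL	CC
1	26000000	28500000	CBD103	CC
3	26000000	28500000	KIT	CC
5	26000000	28500000	ASIP	CC
7	26000000	28500000	TYR	CC
9	26000000	28500000	TYRP1	CC
11	26000000	28500000	MC1R	CC
13	26000000	28500000	SLC45A2	CC
15	26000000	28500000	MFSD12	CC
17	26000000	28500000	AGT	SE
19	26000000	28500000	ADRB2	SE
21	26000000	28500000	ADRB3	SE
23	26000000	28500000	HIF1A	SE
25	26000000	28500000	BDKRB2	SE
27	26000000	28500000	MSTN	SE
29	26000000	28500000	IL6	SE
31	26000000	28500000	ACE	SE
33	26000000	28500000	ACTN3	SE
35	26000000	28500000	PPARGC1A	SE
37	26000000	28500000	EPOR	SE
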