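tf	tp	fn	fp	auc	nTopSites	nSites	nTopOrfs	nOrfs
MCM1_MATALPHA2	1	0	0	1.00	1	1	1	1
PPR1	1	0	0	1.00	1	1	1	1
NDT80	1	0	0	1.00	1	1	1	1
LEU3	5	0	0	1.00	5	5	5	5
MATA1	1	0	0	1.00	1	1	1	1
TFIIA_TBP	1	0	1	0.91	0	1	0	1
GAL4	12	3	0	0.90	12	15	7	7
MCM1	25	1	26	0.86	22	26	18	21
MATALPHA2	5	5	1	0.83	6	10	5	7
TBP	5	2	1	0.81	4	7	4	4
PHO4	4	0	10	0.78	1	4	1	1
PUT3	2	1	0	0.76	2	3	2	2
GCN4	7	11	2	0.72	8	18	5	11
HAP1	8	1	56	0.68	3	9	2	5
RAP1	3	21	0	0.66	11	24	8	18
TFIIA	1	0	6	0.63	0	1	0	1
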