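tf	pdb	nSites	nOrfs	nResidues	lTfbs
GAL4	3coq_A,B	15	7	178	19
GCN4	1ysa_C,D	18	11	114	16
HAP1	1hwt_C,D,G,H	9	5	287	19
LEU3	2ere_A,B	5	5	120	14
MATA1	1yrn_A	1	1	49	13
MATALPHA2	1apl_C	10	7	59	12
MCM1	1mnm_A,B	26	21	166	20
MCM1_MATALPHA2	1mnm_A,B,C,D	1	1	320	25
NDT80	1mnn_A	1	1	290	13
PHO4	1a0a_A,B	4	1	126	16
PPR1	1pyi_A,B	1	1	158	14
PUT3	1zme_C,D	3	2	140	14
RAP1	1ign_A	24	18	189	18
TBP	1ytb_A	7	4	180	12
TFIIA	1ytf_C	1	1	192	13
TFIIA_TBP	1ytf_A,C	1	1	372	15
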