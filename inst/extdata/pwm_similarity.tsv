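tf	prePwm	evenPwm
GAL4	0.15	0.32
GCN4	0.12	0.32
HAP1	0.33	0.40
LEU3	0.22	0.48
MATA1	0.73	0.70
MATALPHA2	0.31	0.64
MCM1	0.34	0.41
NDT80	0.11	0.44
PHO4	0.19	0.54
PUT3	0.40	0.52
RAP1	0.49	0.52
TBP	0.17	0.43
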