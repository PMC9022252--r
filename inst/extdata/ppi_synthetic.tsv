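gene_a	gene_b	score
G0001	G0002	0.95
G0001	G0015	0.92
G0002	G0015	0.41
G0001	G0003	0.85
G0002	G0004	0.62
G0041	G0042	0.97
G0041	G0055	0.88
G0042	G0055	0.93
G0041	G0043	0.45
G0081	G0082	0.91
G0081	G0083	0.52
G0082	G0084	0.40
G0121	G0122	0.96
G0121	G0135	0.61
G0122	G0135	0.94
G0121	G0123	0.39
G0190	G0001	0.90
G0190	G0191	0.77
G0190	G0081	0.48
G0015	G0055	0.43
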