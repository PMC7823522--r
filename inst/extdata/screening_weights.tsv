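type	similarity	mcs	psm	top10	top50
PKS	1	1	0.3	0.53	0.72
NRPS	1	0.4	0.5	0.59	0.72
Mixed	0.4	0.6	0.1	0.45	0.64
All	0.3	0.4	0.1	0.47	0.67
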