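domain_order	functional	type	modification
C-A-PCP	N	NRPS	L
KS-AT-DH-KR-ACP	N	PKS	Enoyl
KS-AT-KR-ACP	N	PKS	Hydroxyl
C-A-PCP-E	N	NRPS	E
KS-AT-DH-ER-KR-ACP	N	PKS	Alkyl
KS-AT-ACP	N	PKS	Ketone
A-PCP	N	NRPS	L
C-A-PCP-TE	N	NRPS	L
KS-tAT_d-KR-ACP	S	PKS	Hydroxyl
KS-tAT_d-DH-KR-ACP	S	PKS	Enoyl
C-A-nMT-PCP	N	NRPS	L
KS-tAT_d-ACP	S	PKS	Alkyl
cAL-ACP	NF	PKS	-
KS-AT-DH-KR-ACP-TE	N	PKS	Enoyl
C-A-ACP	N	Mixed	L
C-PCP	NF	NRPS	-
KS-ACP	S	PKS	Ketone
KS-tAT_d	S	PKS	Ketone
KS-AT	S	PKS	Ketone
KS-tAT_d-DH-KR-cMT-ACP	S	PKS	Enoyl
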