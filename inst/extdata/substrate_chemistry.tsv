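label	kind	fragment	description
malonyl	PK		malonyl-CoA extender, unsubstituted alpha carbon
methylmalonyl	PK	C	methylmalonyl-CoA extender, alpha methyl
ethylmalonyl	PK	CC	ethylmalonyl-CoA extender, alpha ethyl
methoxymalonyl	PK	OC	methoxymalonyl-ACP extender, alpha methoxy
generic	PK		unknown (e.g. trans-AT) extender, treated as malonyl-like
A	NRP	C	alanine
C	NRP	CS	cysteine
D	NRP	CC(O)=O	aspartate
E	NRP	CCC(O)=O	glutamate
F	NRP	Cc1ccccc1	phenylalanine
G	NRP		glycine
H	NRP	Cc1c[nH]cn1	histidine
I	NRP	C(C)CC	isoleucine
K	NRP	CCCCN	lysine
L	NRP	CC(C)C	leucine
N	NRP	CC(N)=O	asparagine
P	NRP_TEMPLATE	N9CCC[C@@H]9	proline (cyclic side chain onto the amide nitrogen)
Q	NRP	CCC(N)=O	glutamine
R	NRP	CCCNC(=N)N	arginine
S	NRP	CO	serine
T	NRP	C(C)O	threonine
V	NRP	C(C)C	valine
W	NRP	Cc1c[nH]c2ccccc12	tryptophan
Y	NRP	Cc1ccc(O)cc1	tyrosine
aad	NRP	CCCC(O)=O	2-amino-adipic acid
bht	NRP	C(O)c1ccc(O)cc1	beta-hydroxy-tyrosine
dab	NRP	CCN	diaminobutyric acid
dhb	ARYL	c1ccc(O)c(O)c1	2,3-dihydroxy-benzoic acid (aryl starter acid)
dhbu	NRP_TEMPLATE	NC(=CC)	2,3-dehydroaminobutyric acid (planar alpha carbon)
dhpg	NRP	c1cc(O)cc(O)c1	3,5-dihydroxy-phenyl-glycine
horn	NRP	CCCNO	hydroxy-L-ornithine
hpg	NRP	c1ccc(O)cc1	4-hydroxy-phenyl-glycine
orn	NRP	CCCN	ornithine
pip	NRP_TEMPLATE	N9CCCC[C@@H]9	pipecolic acid (cyclic side chain onto the amide nitrogen)
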