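name	domT
ACP	13.9
AT	47.4
A	19.6
CAL	221.8
C	25.9
DH2	33.2
DH	31.1
DHt	44.3
ER	68.8
E	60.4
KR	20
KS	72
PCP	21.9
TD	42.1
TE	36.5
bACP	28.9
cMT	104.7
nMT	42.7
oMT	70.6
tAT_d	50
KSQ	72
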