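residue	propensity
A	0.15
C	0.35
D	0.02
E	0.03
F	0.45
G	0.30
H	0.20
I	0.40
K	0.50
L	0.40
M	0.30
N	0.15
P	0.10
Q	0.12
R	0.55
S	0.18
T	0.15
V	0.35
W	0.60
Y	0.30
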