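residue	acp	background
A	0.030	0.05
C	0.030	0.05
D	0.015	0.05
E	0.015	0.05
F	0.100	0.05
G	0.030	0.05
H	0.030	0.05
I	0.030	0.05
K	0.150	0.05
L	0.110	0.05
M	0.030	0.05
N	0.030	0.05
P	0.030	0.05
Q	0.030	0.05
R	0.120	0.05
S	0.030	0.05
T	0.030	0.05
V	0.030	0.05
W	0.100	0.05
Y	0.030	0.05
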