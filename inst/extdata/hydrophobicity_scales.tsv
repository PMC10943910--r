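residue	kd	eisenberg
A	1.8	0.62
C	2.5	0.29
D	-3.5	-0.90
E	-3.5	-0.74
F	2.8	1.19
G	-0.4	0.48
H	-3.2	-0.40
I	4.5	1.38
K	-3.9	-1.50
L	3.8	1.06
M	1.9	0.64
N	-3.5	-0.78
P	-1.6	0.12
Q	-3.5	-0.85
R	-4.5	-2.53
S	-0.8	-0.18
T	-0.7	-0.05
V	4.2	1.08
W	-0.9	0.81
Y	-1.3	0.26
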