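amino_acid	amount_mg_per_g
E	37.02
L	23.68
A	23.35
D	21.18
V	17.78
F	17.01
P	8.68
I	13.07
K	13.44
G	14.91
S	5.27
H	6.83
T	6.77
Y	7.26
R	5.10
M	5.82
C	1.59
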