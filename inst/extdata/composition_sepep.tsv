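amino_acid	amount_mg_per_g
E	40.99
L	30.33
A	29.28
D	25.92
V	23.64
F	20.84
P	15.85
I	15.51
K	14.89
G	13.98
S	9.55
H	9.38
T	9.2
Y	8.44
R	8.15
M	6.93
C	0.9
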