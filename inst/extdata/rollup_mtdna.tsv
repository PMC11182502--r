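prefix	major
M7	M7
M71	M71
M24	M24
M	M
D	M
G	M
E	M
Q	M
C	M
Z	M
B	B
F1	F1
F	F
R9	F
R	R
N	N
A	N
Y	N
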