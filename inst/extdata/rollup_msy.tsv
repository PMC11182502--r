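prefix	major
O1b	O1b
O1a	O1a
O2a	O2a
O	O
N	N
C	C
D	D
J	J
R	R
Q	Q
F	F
K	K
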