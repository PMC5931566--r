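group	pka
Nterm	7.5
Cterm	3.55
D	4.05
E	4.45
C	9
Y	10
H	5.98
K	10
R	12
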