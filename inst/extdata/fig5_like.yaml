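# Default synthetic-proteome design (fig5-like composition bias)
n-proteins: 150
seed: 1
# ordered composition: A=0.05 C=0.04 D=0.005 E=0.005 F=0.09 G=0.05 H=0.005 I=0.18 K=0.005 L=0.18 M=0.05 N=0.005 P=0.005 Q=0.005 R=0.005 S=0.05 T=0.06 V=0.14 W=0.02 Y=0.05
# disordered composition: A=0.08 C=0.002 D=0.075 E=0.19 F=0.002 G=0.12 H=0.01 I=0.003 K=0.15 L=0.005 M=0.003 N=0.03 P=0.07 Q=0.04 R=0.06 S=0.11 T=0.04 V=0.004 W=0.002 Y=0.004
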