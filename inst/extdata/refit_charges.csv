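label,charge
C1,0.3807
HO1,0.4278
O1,-0.6496
C2,0.3003
O2,-0.6958
HO2,0.4496
C3,0.2904
O3,-0.7011
HO3,0.4365
C4,0.2602
O4,-0.7168
HO4,0.4256
C5,0.2169
O5,-0.4806
C6,0.2861
O6,-0.6717
HO6,0.4413
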