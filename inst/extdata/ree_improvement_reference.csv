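parameter_class,mean_ree,delta
baseline,3.744,NA
charge_and_dihedral,0.282,3.463
charge_only,2.964,0.781
dihedral_only,1.064,2.681
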