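    0    0    2

Synthetic GLYCAM-role starting charges for beta-d-glucose
BGC.res
BGC   INT  0
CORRECT  OMIT DU   BEG
  0.0000
   1  DUMM  DU    M      0  -1  -2     0.000     0.000     0.000    0.00000
   2  DUMM  DU    M      1   0  -1     1.449     0.000     0.000    0.00000
   3  DUMM  DU    M      2   1   0     1.522   111.100     0.000    0.00000
   4  C1    Cg    M      0   0   0     0.000     0.000     0.000    0.40000
   5  C2    Cg    M      0   0   0     0.000     0.000     0.000    0.29000
   6  C3    Cg    M      0   0   0     0.000     0.000     0.000    0.28000
   7  C4    Cg    M      0   0   0     0.000     0.000     0.000    0.26000
   8  C5    Cg    M      0   0   0     0.000     0.000     0.000    0.22000
   9  C6    Cg    M      0   0   0     0.000     0.000     0.000    0.28000
  10  O1    Oh    M      0   0   0     0.000     0.000     0.000   -0.64000
  11  O2    Oh    M      0   0   0     0.000     0.000     0.000   -0.69000
  12  O3    Oh    M      0   0   0     0.000     0.000     0.000   -0.70000
  13  O4    Oh    M      0   0   0     0.000     0.000     0.000   -0.71000
  14  O5    Os    M      0   0   0     0.000     0.000     0.000   -0.47000
  15  O6    Oh    M      0   0   0     0.000     0.000     0.000   -0.68000
  16  H1    H1    M      0   0   0     0.000     0.000     0.000    0.00000
  17  H2    H1    M      0   0   0     0.000     0.000     0.000    0.00000
  18  H3    H1    M      0   0   0     0.000     0.000     0.000    0.00000
  19  H4    H1    M      0   0   0     0.000     0.000     0.000    0.00000
  20  H5    H1    M      0   0   0     0.000     0.000     0.000    0.00000
  21  H61   H1    M      0   0   0     0.000     0.000     0.000    0.00000
  22  H62   H1    M      0   0   0     0.000     0.000     0.000    0.00000
  23  HO1   Ho    M      0   0   0     0.000     0.000     0.000    0.42000
  24  HO2   Ho    M      0   0   0     0.000     0.000     0.000    0.44000
  25  HO3   Ho    M      0   0   0     0.000     0.000     0.000    0.43000
  26  HO4   Ho    M      0   0   0     0.000     0.000     0.000    0.43000
  27  HO6   Ho    M      0   0   0     0.000     0.000     0.000    0.44000

DONE
STOP
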