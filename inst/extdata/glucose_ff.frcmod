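Synthetic GLYCAM-role starting parameter set for beta-d-glucose
MASS
Cg         12.0100
Oh         16.0000
Os         16.0000
H1          1.0080
Ho          1.0080

BOND
Cg-Cg      310.0000    1.5200
Cg-H1      340.0000    1.0900
Cg-Oh      320.0000    1.4100
Cg-Os      320.0000    1.4100
Ho-Oh      553.0000    0.9600

ANGLE
Cg-Cg-Cg    45.0000  111.0000
Cg-Cg-H1    45.0000  111.0000
Cg-Cg-Oh    70.0000  107.5000
Cg-Cg-Os    70.0000  108.5000
Cg-Oh-Ho    55.0000  109.5000
Cg-Os-Cg    62.0000  113.5000
H1-Cg-H1    40.0000  109.5000
H1-Cg-Oh    60.0000  110.0000
H1-Cg-Os    60.0000  110.0000
Oh-Cg-Os    75.0000  110.0000

DIHE
Cg-Cg-Cg-Cg   1    0.4500    0.0000   3.0   SCEE=1.0 SCNB=1.0
Cg-Cg-Cg-Oh   1    0.3000    0.0000   3.0
Cg-Cg-Cg-Os   1    0.2500    0.0000   3.0
Cg-Cg-Cg-H1   1    0.1500    0.0000   3.0
Oh-Cg-Cg-Oh   1    0.8000    0.0000  -2.0
Oh-Cg-Cg-Oh   1    0.3000    0.0000   3.0
Oh-Cg-Cg-Os   1    0.6000    0.0000  -1.0
Oh-Cg-Cg-Os   1    0.9500    0.0000  -2.0
Oh-Cg-Cg-Os   1    0.2000    0.0000   3.0
H1-Cg-Cg-Oh   1    0.2000    0.0000   3.0
H1-Cg-Cg-Os   1    0.2000    0.0000   3.0
H1-Cg-Cg-H1   1    0.1700    0.0000   3.0
Cg-Cg-Os-Cg   1    0.5000    0.0000  -2.0
Cg-Cg-Os-Cg   1    0.4000    0.0000   3.0
Cg-Os-Cg-Oh   1    0.8500    0.0000  -1.0
Cg-Os-Cg-Oh   1    0.6000    0.0000   2.0
Cg-Os-Cg-H1   1    0.2500    0.0000   3.0
Cg-Cg-Oh-Ho   1    0.1800    0.0000  -3.0
Cg-Cg-Oh-Ho   1    0.4500    0.0000   1.0
Ho-Oh-Cg-Os   1    0.3000    0.0000  -3.0
Ho-Oh-Cg-Os   1    0.5500    0.0000   1.0
H1-Cg-Oh-Ho   1    0.2000    0.0000   3.0

NONBON
Cg          1.9080    0.1094
Oh          1.7210    0.2104
Os          1.6837    0.1700
H1          1.3870    0.0157
Ho          0.0000    0.0000
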