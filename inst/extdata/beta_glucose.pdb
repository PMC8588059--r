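REMARK   beta-D-glucopyranose, 4C1 chair, MMFF94-relaxed synthetic geometry
HETATM    1  C1  BGC A   1      -0.888  -1.493   0.021  1.00  0.00           C
HETATM    2  C2  BGC A   1      -1.296  -0.395   1.016  1.00  0.00           C
HETATM    3  C3  BGC A   1      -0.984   0.971   0.415  1.00  0.00           C
HETATM    4  C4  BGC A   1       0.483   1.034  -0.017  1.00  0.00           C
HETATM    5  C5  BGC A   1       0.792  -0.135  -0.965  1.00  0.00           C
HETATM    6  C6  BGC A   1       2.262  -0.151  -1.418  1.00  0.00           C
HETATM    7  O1  BGC A   1      -1.093  -2.749   0.651  1.00  0.00           O
HETATM    8  O2  BGC A   1      -2.696  -0.464   1.327  1.00  0.00           O
HETATM    9  O3  BGC A   1      -1.236   2.013   1.371  1.00  0.00           O
HETATM   10  O4  BGC A   1       0.738   2.290  -0.649  1.00  0.00           O
HETATM   11  O5  BGC A   1       0.481  -1.392  -0.334  1.00  0.00           O
HETATM   12  O6  BGC A   1       3.174  -0.088  -0.323  1.00  0.00           O
HETATM   13  H1  BGC A   1      -1.519  -1.472  -0.876  1.00  0.00           H
HETATM   14  H2  BGC A   1      -0.761  -0.517   1.966  1.00  0.00           H
HETATM   15  H3  BGC A   1      -1.644   1.183  -0.435  1.00  0.00           H
HETATM   16  H4  BGC A   1       1.115   0.987   0.879  1.00  0.00           H
HETATM   17  H5  BGC A   1       0.183  -0.053  -1.875  1.00  0.00           H
HETATM   18  H61 BGC A   1       2.477   0.688  -2.089  1.00  0.00           H
HETATM   19  H62 BGC A   1       2.474  -1.080  -1.955  1.00  0.00           H
HETATM   20  HO1 BGC A   1      -0.664  -3.386   0.054  1.00  0.00           H
HETATM   21  HO2 BGC A   1      -2.847  -1.393   1.597  1.00  0.00           H
HETATM   22  HO3 BGC A   1      -2.110   1.798   1.756  1.00  0.00           H
HETATM   23  HO4 BGC A   1       0.327   2.957  -0.060  1.00  0.00           H
HETATM   24  HO6 BGC A   1       3.232   0.847  -0.056  1.00  0.00           H
END
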