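REMARK   SYNTHETIC coordinates: ideal-geometry backbone fragment, residues 41-43.
REMARK   NOT the deposited PDB entry 2ES9. The temperature-factor column carries
REMARK   the published backbone B-factors for O/C of residue 42 and N of residue 43
REMARK   (22.15 / 21.83 / 21.47 A^2); all other fields are synthetic stand-ins.
ATOM      1  N   ALA A  41       0.000   0.000   0.000  1.00 21.09           N
ATOM      2  CA  ALA A  41       1.458   0.000   0.000  1.00 21.59           C
ATOM      3  C   ALA A  41       2.009   1.422   0.000  1.00 21.46           C
ATOM      4  O   ALA A  41       2.910   1.749   0.773  1.00 21.68           O
ATOM      5  CB  ALA A  41       1.986  -0.766   1.203  1.00 21.53           C
ATOM      6  N   ALA A  42       1.463   2.263  -0.872  1.00 21.34           N
ATOM      7  CA  ALA A  42       1.899   3.650  -0.974  1.00 21.24           C
ATOM      8  C   ALA A  42       1.768   4.370   0.364  1.00 21.83           C
ATOM      9  O   ALA A  42       2.689   5.059   0.802  1.00 22.15           O
ATOM     10  CB  ALA A  42       3.337   3.718  -1.465  1.00 21.55           C
ATOM     11  N   ALA A  43       0.618   4.205   1.008  1.00 21.47           N
ATOM     12  CA  ALA A  43       0.364   4.838   2.297  1.00 21.95           C
ATOM     13  C   ALA A  43       1.421   4.443   3.323  1.00 21.26           C
ATOM     14  O   ALA A  43       1.961   5.294   4.030  1.00 21.87           O
ATOM     15  CB  ALA A  43       0.323   6.350   2.144  1.00 21.60           C
END
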