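REMARK   synthetic two-residue golden fixture with round coordinates
ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  GLY A   1       1.500   0.000   0.000  1.00  0.00           C
ATOM      3  C   GLY A   1       1.500   1.500   0.000  1.00  0.00           C
ATOM      4  O   GLY A   1       2.500   2.000   0.000  1.00  0.00           O
ATOM      5  N   ALA A   2       0.500   2.200   0.000  1.00  0.00           N
ATOM      6  CA  ALA A   2       0.500   3.700   0.000  1.00  0.00           C
ATOM      7  C   ALA A   2       1.900   4.200   0.000  1.00  0.00           C
ATOM      8  O   ALA A   2       2.900   3.600   0.000  1.00  0.00           O
ATOM      9  CB  ALA A   2      -0.400   4.200   1.200  1.00  0.00           C
END
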