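ATOM      1 N    ALA A   1       0.000   4.500   0.000  1.00  0.00
ATOM      2 CA   ALA A   1       1.450   4.800   0.000  1.00  0.00
ATOM      3 C    ALA A   1       2.400   3.900   0.600  1.00  0.00
ATOM      4 O    ALA A   1       2.300   2.700   0.700  1.00  0.00
ATOM      5 CB   ALA A   1       1.600   5.700   1.200  1.00  0.00
ATOM      6 N    GLY A   2       3.800   4.500   0.000  1.00  0.00
ATOM      7 CA   GLY A   2       5.250   4.800   0.000  1.00  0.00
ATOM      8 C    GLY A   2       6.200   3.900   0.600  1.00  0.00
ATOM      9 O    GLY A   2       6.100   2.700   0.700  1.00  0.00
ATOM     10 N    ALA A   3       7.600   4.500   0.000  1.00  0.00
ATOM     11 CA   ALA A   3       9.050   4.800   0.000  1.00  0.00
ATOM     12 C    ALA A   3      10.000   3.900   0.600  1.00  0.00
ATOM     13 O    ALA A   3       9.900   2.700   0.700  1.00  0.00
ATOM     14 CB   ALA A   3       9.200   5.700   1.200  1.00  0.00
HETATM   15 C1   BNZ A  90       5.190   0.500   0.200  1.00  0.00
HETATM   16 C2   BNZ A  90       4.495   1.704   0.200  1.00  0.00
HETATM   17 C3   BNZ A  90       3.105   1.704   0.200  1.00  0.00
HETATM   18 C4   BNZ A  90       2.410   0.500   0.200  1.00  0.00
HETATM   19 C5   BNZ A  90       3.105  -0.704   0.200  1.00  0.00
HETATM   20 C6   BNZ A  90       4.495  -0.704   0.200  1.00  0.00
HETATM   21 O    HOH A  91       9.000   9.000   9.000  1.00  0.00
HETATM   22 O    HOH A  92      -5.000   8.000   2.000  1.00  0.00
HETATM   23 NA   NA  A  93       8.000  -6.000   3.000  1.00  0.00
END
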