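ATOM      1  OD1 ASP A   1      -0.037   2.164   1.883  1.00  0.00           O
ATOM      2  OD1 ASP A   2       0.103  -2.735   0.852  1.00  0.00           O
ATOM      3  NZ  LYS A   3      -0.110  -0.305  -2.877  1.00  0.00           N
ATOM      4  CB  ALA A   4      -0.970   3.659  -0.508  1.00  0.00           C
ATOM      5  OD1 ASP A   5       6.432  -2.202   1.227  1.00  0.00           O
ATOM      6  CB  ALA A   6       3.440   1.980   2.736  1.00  0.00           C
ATOM      7  CB  ALA A   7       3.851  -3.268   1.783  1.00  0.00           C
ATOM      8  CB  ALA A   8      12.348   0.095  -2.530  1.00  0.00           C
ATOM      9  CB  ALA A   9      10.310  -2.965   2.408  1.00  0.00           C
ATOM     10  CB  ALA A  10      10.255   3.613   0.791  1.00  0.00           C
ATOM     11  CB  ALA A  11       8.026   1.698  -2.598  1.00  0.00           C
END
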