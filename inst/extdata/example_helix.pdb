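EXPDTA    X-RAY DIFFRACTION
REMARK   2 RESOLUTION.    1.50 ANGSTROMS.
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.422   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       2.910   1.749  -0.773  1.00  0.00           O
ATOM      5  CB  ALA A   1       1.968  -0.721   1.249  1.00  0.00           C
ATOM      6  N   VAL A   2       1.463   2.263   0.872  1.00  0.00           N
ATOM      7  CA  VAL A   2       1.899   3.650   0.974  1.00  0.00           C
ATOM      8  C   VAL A   2       1.768   4.370  -0.364  1.00  0.00           C
ATOM      9  O   VAL A   2       2.689   5.059  -0.802  1.00  0.00           O
ATOM     10  CB  VAL A   2       1.039   4.379   2.007  1.00  0.00           C
ATOM     11  CG1 VAL A   2       1.495   5.836   2.115  1.00  0.00           C
ATOM     12  CG2 VAL A   2       1.186   3.697   3.367  1.00  0.00           C
ATOM     13  N   LEU A   3       0.618   4.205  -1.008  1.00  0.00           N
ATOM     14  CA  LEU A   3       0.364   4.838  -2.297  1.00  0.00           C
ATOM     15  C   LEU A   3       1.421   4.443  -3.323  1.00  0.00           C
ATOM     16  O   LEU A   3       1.961   5.294  -4.030  1.00  0.00           O
ATOM     17  CB  LEU A   3      -1.006   4.402  -2.816  1.00  0.00           C
ATOM     18  CG  LEU A   3      -1.274   5.065  -4.169  1.00  0.00           C
ATOM     19  CD1 LEU A   3      -2.646   4.628  -4.689  1.00  0.00           C
ATOM     20  CD2 LEU A   3      -0.194   4.646  -5.166  1.00  0.00           C
ATOM     21  N   LYS A   4       1.711   3.149  -3.398  1.00  0.00           N
ATOM     22  CA  LYS A   4       2.704   2.639  -4.337  1.00  0.00           C
ATOM     23  C   LYS A   4       4.057   3.309  -4.126  1.00  0.00           C
ATOM     24  O   LYS A   4       4.701   3.745  -5.081  1.00  0.00           O
ATOM     25  CB  LYS A   4       2.869   1.132  -4.135  1.00  0.00           C
ATOM     26  CG  LYS A   4       3.912   0.598  -5.121  1.00  0.00           C
ATOM     27  CD  LYS A   4       4.078  -0.911  -4.920  1.00  0.00           C
ATOM     28  CE  LYS A   4       5.119  -1.445  -5.904  1.00  0.00           C
ATOM     29  NZ  LYS A   4       5.279  -2.893  -5.712  1.00  0.00           N
ATOM     30  N   ASP A   5       4.484   3.388  -2.870  1.00  0.00           N
ATOM     31  CA  ASP A   5       5.761   4.005  -2.531  1.00  0.00           C
ATOM     32  C   ASP A   5       5.830   5.442  -3.035  1.00  0.00           C
ATOM     33  O   ASP A   5       6.820   5.851  -3.640  1.00  0.00           O
ATOM     34  CB  ASP A   5       5.938   4.011  -1.011  1.00  0.00           C
ATOM     35  CG  ASP A   5       7.258   4.648  -0.662  1.00  0.00           C
ATOM     36  OD1 ASP A   5       7.591   4.752   0.495  1.00  0.00           O
ATOM     37  OD2 ASP A   5       8.064   5.100  -1.635  1.00  0.00           O
ATOM     38  N   GLU A   6       4.771   6.204  -2.781  1.00  0.00           N
ATOM     39  CA  GLU A   6       4.709   7.597  -3.208  1.00  0.00           C
ATOM     40  C   GLU A   6       4.899   7.721  -4.716  1.00  0.00           C
ATOM     41  O   GLU A   6       5.674   8.553  -5.187  1.00  0.00           O
ATOM     42  CB  GLU A   6       3.345   8.184  -2.839  1.00  0.00           C
ATOM     43  CG  GLU A   6       3.282   9.646  -3.288  1.00  0.00           C
ATOM     44  CD  GLU A   6       1.938  10.224  -2.925  1.00  0.00           C
ATOM     45  OE1 GLU A   6       1.683  11.375  -3.194  1.00  0.00           O
ATOM     46  OE2 GLU A   6       1.024   9.462  -2.304  1.00  0.00           O
ATOM     47  N   CYS A   7       4.187   6.887  -5.467  1.00  0.00           N
ATOM     48  CA  CYS A   7       4.276   6.902  -6.922  1.00  0.00           C
ATOM     49  C   CYS A   7       5.712   6.685  -7.389  1.00  0.00           C
ATOM     50  O   CYS A   7       6.209   7.406  -8.254  1.00  0.00           O
ATOM     51  CB  CYS A   7       3.403   5.787  -7.498  1.00  0.00           C
ATOM     52  SG  CYS A   7       3.514   5.805  -9.308  1.00  0.00           S
ATOM     53  N   PHE A   8       6.372   5.687  -6.812  1.00  0.00           N
ATOM     54  CA  PHE A   8       7.751   5.373  -7.167  1.00  0.00           C
ATOM     55  C   PHE A   8       8.660   6.581  -6.968  1.00  0.00           C
ATOM     56  O   PHE A   8       9.464   6.915  -7.839  1.00  0.00           O
ATOM     57  CB  PHE A   8       8.257   4.229  -6.287  1.00  0.00           C
ATOM     58  CG  PHE A   8       9.680   3.905  -6.654  1.00  0.00           C
ATOM     59  CD1 PHE A   8      10.354   2.898  -5.989  1.00  0.00           C
ATOM     60  CD2 PHE A   8      10.317   4.618  -7.653  1.00  0.00           C
ATOM     61  CE1 PHE A   8      11.661   2.601  -6.326  1.00  0.00           C
ATOM     62  CE2 PHE A   8      11.623   4.318  -7.991  1.00  0.00           C
ATOM     63  CZ  PHE A   8      12.295   3.310  -7.326  1.00  0.00           C
ATOM     64  N   GLY A   9       8.528   7.232  -5.817  1.00  0.00           N
ATOM     65  CA  GLY A   9       9.336   8.403  -5.502  1.00  0.00           C
ATOM     66  C   GLY A   9       9.171   9.489  -6.560  1.00  0.00           C
ATOM     67  O   GLY A   9      10.153  10.060  -7.036  1.00  0.00           O
ATOM     68  N   HIS A  10       7.924   9.768  -6.925  1.00  0.00           N
ATOM     69  CA  HIS A  10       7.629  10.785  -7.927  1.00  0.00           C
ATOM     70  C   HIS A  10       8.339  10.485  -9.243  1.00  0.00           C
ATOM     71  O   HIS A  10       8.957  11.366  -9.841  1.00  0.00           O
ATOM     72  CB  HIS A  10       6.118  10.904  -8.165  1.00  0.00           C
ATOM     73  CG  HIS A  10       5.764  11.947  -9.198  1.00  0.00           C
ATOM     74  ND1 HIS A  10       4.472  12.175  -9.522  1.00  0.00           N
ATOM     75  CD2 HIS A  10       6.559  12.752  -9.912  1.00  0.00           C
ATOM     76  CE1 HIS A  10       4.447  13.136 -10.452  1.00  0.00           C
ATOM     77  NE2 HIS A  10       5.711  13.495 -10.698  1.00  0.00           N
ATOM     78  N   TRP A  11       8.247   9.236  -9.688  1.00  0.00           N
ATOM     79  CA  TRP A  11       8.881   8.818 -10.933  1.00  0.00           C
ATOM     80  C   TRP A  11      10.381   9.091 -10.908  1.00  0.00           C
ATOM     81  O   TRP A  11      10.939   9.635 -11.861  1.00  0.00           O
ATOM     82  CB  TRP A  11       8.662   7.319 -11.139  1.00  0.00           C
ATOM     83  CG  TRP A  11       9.317   6.889 -12.426  1.00  0.00           C
ATOM     84  CD1 TRP A  11       9.335   5.648 -12.937  1.00  0.00           C
ATOM     85  CD2 TRP A  11      10.061   7.744 -13.353  1.00  0.00           C
ATOM     86  NE1 TRP A  11      10.025   5.640 -14.119  1.00  0.00           N
ATOM     87  CE2 TRP A  11      10.481   6.907 -14.403  1.00  0.00           C
ATOM     88  CE3 TRP A  11      10.379   9.103 -13.377  1.00  0.00           C
ATOM     89  CZ2 TRP A  11      11.219   7.447 -15.451  1.00  0.00           C
ATOM     90  CZ3 TRP A  11      11.105   9.612 -14.416  1.00  0.00           C
ATOM     91  CH2 TRP A  11      11.525   8.790 -15.452  1.00  0.00           C
ATOM     92  N   MET A  12      11.028   8.711  -9.811  1.00  0.00           N
ATOM     93  CA  MET A  12      12.464   8.914  -9.659  1.00  0.00           C
ATOM     94  C   MET A  12      12.832  10.386  -9.813  1.00  0.00           C
ATOM     95  O   MET A  12      13.773  10.729 -10.528  1.00  0.00           O
ATOM     96  CB  MET A  12      12.900   8.443  -8.271  1.00  0.00           C
ATOM     97  CG  MET A  12      14.405   8.655  -8.110  1.00  0.00           C
ATOM     98  SD  MET A  12      14.922   8.096  -6.463  1.00  0.00           S
ATOM     99  CE  MET A  12      16.697   8.456  -6.550  1.00  0.00           C
END
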