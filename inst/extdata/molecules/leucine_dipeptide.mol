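leucine_dipeptide
     RDKit          2D

 16 15  0  0  0  0  0  0  0  0999 V2000
   -5.0008    0.8525    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5090    0.6956    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6272    1.9091    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8990   -0.6747    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4072   -0.8316    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7972   -2.2020    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6946   -2.3589    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3046   -3.7293    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5763   -1.1454    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5254    0.3818    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1354    1.7522    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.9663    0.2249    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.8481    1.4384    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3399    1.2815    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.9499   -0.0889    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    4.2216    2.4949    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  2  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  7  8  1  0
  7  9  1  0
  5 10  1  0
 10 11  2  0
 10 12  1  0
 12 13  1  0
 13 14  1  0
 14 15  2  0
 14 16  1  0
M  END
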