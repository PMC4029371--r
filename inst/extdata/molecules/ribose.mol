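ribose
     RDKit          2D

 10 10  0  0  0  0  0  0  0  0999 V2000
    3.4433    0.9054    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.4992   -0.2603    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0177   -0.0255    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3368    1.3111    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1447    1.0765    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2053    2.1373    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3795   -0.4050    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7160   -1.0859    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0430   -1.0861    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1915   -2.5676    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  5  7  1  0
  7  8  1  0
  7  9  1  0
  9 10  1  0
  9  3  1  0
M  END
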