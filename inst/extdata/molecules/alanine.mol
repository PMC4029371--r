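alanine
     RDKit          2D

  6  5  0  0  0  0  0  0  0  0999 V2000
    1.5000    1.2990    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7500    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5000   -1.2990    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7500   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5000    1.2990    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5000   -1.2990    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  2  4  1  0
  4  5  2  0
  4  6  1  0
M  END
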