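acetylacetone
     RDKit          2D

  7  6  0  0  0  0  0  0  0  0999 V2000
   -2.5981   -0.8571    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2990   -0.1071    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2990    1.3929    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.8571    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2990   -0.1071    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5981   -0.8571    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2990    1.3929    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  2  4  1  0
  4  5  1  0
  5  6  1  0
  5  7  2  0
M  END
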