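methyl_phosphate
     RDKit          2D

  6  5  0  0  0  0  0  0  0  0999 V2000
   -2.1651    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8660    0.7500    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.4330    0.0000    0.0000 P   0  0  0  0  0  0  0  0  0  0  0  0
    1.1830    1.2990    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3170   -1.2990    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.7321   -0.7500    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  2  0
  3  5  1  0
  3  6  1  0
M  END
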