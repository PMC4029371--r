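adenine
     RDKit          2D

 10 11  0  0  0  0  0  0  0  0999 V2000
    1.6198    2.3424    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.2034    0.9014    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2432   -0.1798    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.8268   -1.6208    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3706   -1.9807    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6692   -0.8996    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1684   -0.9489    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6786    0.4617    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4947    1.3828    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2528    0.5415    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  2  0
  5  6  1  0
  6  7  1  0
  7  8  1  0
  8  9  2  0
  9 10  1  0
 10  2  1  0
 10  6  2  0
M  END
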