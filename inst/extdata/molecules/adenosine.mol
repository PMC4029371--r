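adenosine
     RDKit          2D

 19 21  0  0  0  0  0  0  0  0999 V2000
   -6.0109   -0.2464    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.8415   -1.1859    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4432   -0.6429    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1820   -1.4550    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0200   -0.5065    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4304   -0.8891    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.9734   -2.2874    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4710   -2.2031    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.8536   -0.7527    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1875   -0.0665    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.4486   -0.8786    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    4.2602    1.4317    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.9990    2.2438    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6651    1.5576    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.5924    0.0594    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5630    0.8918    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7509    2.1529    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0606    0.8075    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.0091    1.9695    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  7  8  2  0
  8  9  1  0
  9 10  2  0
 10 11  1  0
 10 12  1  0
 12 13  2  0
 13 14  1  0
 14 15  2  0
  5 16  1  0
 16 17  1  0
 16 18  1  0
 18 19  1  0
 18  3  1  0
 15  6  1  0
 15  9  1  0
M  END
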