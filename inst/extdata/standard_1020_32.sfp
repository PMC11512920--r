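Fp1 -2.938926261e-01  9.045084972e-01 3.090169944e-01
Fp2  2.938926261e-01  9.045084972e-01 3.090169944e-01
F7 -7.694208843e-01  5.590169944e-01 3.090169944e-01
F3 -4.330274292e-01  6.454163629e-01 6.292256862e-01
Fz  0.000000000e+00  5.877852523e-01 8.090169944e-01
F4  4.330274292e-01  6.454163629e-01 6.292256862e-01
F8  7.694208843e-01  5.590169944e-01 3.090169944e-01
FC5 -7.564688004e-01  3.427981057e-01 5.569958821e-01
FC1 -2.839429504e-01  3.506992531e-01 8.924048604e-01
FC2  2.839429504e-01  3.506992531e-01 8.924048604e-01
FC6  7.564688004e-01  3.427981057e-01 5.569958821e-01
T7 -9.510565163e-01  5.823541592e-17 3.090169944e-01
C3 -5.877852523e-01  3.599146639e-17 8.090169944e-01
Cz  0.000000000e+00  0.000000000e+00 1.000000000e+00
C4  5.877852523e-01  3.599146639e-17 8.090169944e-01
T8  9.510565163e-01  5.823541592e-17 3.090169944e-01
TP9 -9.510565163e-01 -3.090169944e-01 6.123233996e-17
CP5 -7.564688004e-01 -3.427981057e-01 5.569958821e-01
CP1 -2.839429504e-01 -3.506992531e-01 8.924048604e-01
CP2  2.839429504e-01 -3.506992531e-01 8.924048604e-01
CP6  7.564688004e-01 -3.427981057e-01 5.569958821e-01
TP10  9.510565163e-01 -3.090169944e-01 6.123233996e-17
P7 -7.694208843e-01 -5.590169944e-01 3.090169944e-01
P3 -4.330274292e-01 -6.454163629e-01 6.292256862e-01
Pz  7.198293278e-17 -5.877852523e-01 8.090169944e-01
P4  4.330274292e-01 -6.454163629e-01 6.292256862e-01
P8  7.694208843e-01 -5.590169944e-01 3.090169944e-01
PO9 -5.877852523e-01 -8.090169944e-01 6.123233996e-17
O1 -2.938926261e-01 -9.045084972e-01 3.090169944e-01
Oz  1.164708318e-16 -9.510565163e-01 3.090169944e-01
O2  2.938926261e-01 -9.045084972e-01 3.090169944e-01
PO10  5.877852523e-01 -8.090169944e-01 6.123233996e-17
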