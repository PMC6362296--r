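"energy_keV","pe","compton","rayleigh","total"
10,4.2158,0.207892,0.436881,4.86058
11.5,2.68595,0.206753,0.334994,3.2277
13.22,1.71335,0.205466,0.257053,2.17587
15.2,1.0914,0.204011,0.197179,1.49259
17.48,0.689352,0.202369,0.151194,1.04291
20.09,0.43618,0.200532,0.116065,0.752777
23.1,0.273985,0.198467,0.0890225,0.561475
26.56,0.172124,0.196163,0.0682856,0.436573
30.54,0.108137,0.1936,0.0523735,0.35411
35.11,0.0680827,0.190766,0.0401832,0.299032
40.37,0.0428955,0.187639,0.0308213,0.261356
46.42,0.0274943,0.184211,0.0236387,0.235344
53.37,0.0179915,0.180477,0.0181342,0.216603
61.36,0.0122076,0.176434,0.0139117,0.202553
70.55,0.00886793,0.172082,0.0106713,0.191621
81.11,0.00651132,0.167436,0.00818693,0.182134
93.26,0.00526271,0.162505,0.00627974,0.174048
107.23,0.00450672,0.157319,0.00481683,0.166642
123.28,0.00408925,0.15191,0.00369544,0.159695
141.75,0.00371013,0.146307,0.00283445,0.152851
162.98,0.00346498,0.140556,0.00217424,0.146195
187.38,0.00330047,0.134701,0.00166797,0.139669
215.44,0.00315806,0.128782,0.00127951,0.13322
247.71,0.00303384,0.122841,0.000981454,0.126857
284.8,0.00291454,0.116922,0.000752899,0.120589
327.45,0.00279293,0.111055,0.000577547,0.114425
376.49,0.00267241,0.105271,0.000443028,0.108386
432.88,0.00256886,0.099593,0.000339832,0.102502
497.7,0.00247804,0.0940426,0.00026069,0.0967813
572.24,0.00234009,0.088631,0.00019997,0.091171
657.93,0.00221313,0.0833704,0.000153399,0.0857369
756.46,0.00209545,0.0782671,0.000117671,0.0804803
869.75,0.00198645,0.0733275,9.02637e-05,0.0754042
1000,0.00188467,0.0685567,6.92409e-05,0.0705106
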