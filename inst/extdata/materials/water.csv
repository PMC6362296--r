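"energy_keV","pe","compton","rayleigh","total"
10,4.67802,0.214102,0.436881,5.329
11.5,2.97684,0.212929,0.334994,3.52477
13.22,1.89663,0.211604,0.257053,2.36528
15.2,1.20642,0.210105,0.197179,1.6137
17.48,0.759253,0.208414,0.151194,1.11886
20.09,0.47856,0.206522,0.116065,0.801147
23.1,0.297082,0.204396,0.0890225,0.5905
26.56,0.184446,0.202023,0.0682856,0.454755
30.54,0.11416,0.199383,0.0523735,0.365917
35.11,0.0693124,0.196464,0.0401832,0.30596
40.37,0.041979,0.193244,0.0308213,0.266044
46.42,0.0247347,0.189713,0.0236387,0.238087
53.37,0.0143726,0.185868,0.0181342,0.218375
61.36,0.00810247,0.181704,0.0139117,0.203718
70.55,0.0042465,0.177222,0.0106713,0.19214
81.11,0.00214992,0.172437,0.00818693,0.182774
93.26,0.000790719,0.167359,0.00627974,0.17443
107.23,0.000165699,0.162018,0.00481683,0.167
123.28,1.98193e-05,0.156448,0.00369544,0.160163
141.75,2.3661e-06,0.150677,0.00283445,0.153514
162.98,1e-06,0.144754,0.00217424,0.14693
187.38,1e-06,0.138725,0.00166797,0.140394
215.44,1e-06,0.132629,0.00127951,0.133909
247.71,1e-06,0.126511,0.000981454,0.127493
284.8,1e-06,0.120414,0.000752899,0.121168
327.45,1e-06,0.114372,0.000577547,0.11495
376.49,1e-06,0.108415,0.000443028,0.108859
432.88,1e-06,0.102568,0.000339832,0.102909
497.7,1e-06,0.0968516,0.00026069,0.0971133
572.24,1e-06,0.0912784,0.00019997,0.0914794
657.93,1e-06,0.0858607,0.000153399,0.086015
756.46,1e-06,0.080605,0.000117671,0.0807237
869.75,4.2062e-06,0.0755178,9.02637e-05,0.0756122
1000,4.62799e-05,0.0706045,6.92409e-05,0.07072
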