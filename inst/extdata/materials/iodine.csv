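"energy_keV","pe","compton","rayleigh","total"
10,211.274,0.161088,4.36881,215.804
11.5,138.916,0.160205,3.34994,142.426
13.22,91.4433,0.159208,2.57053,94.173
15.2,60.161,0.158081,1.97179,62.2909
17.48,39.5569,0.156809,1.51194,41.2256
20.09,26.0559,0.155385,1.16065,27.3719
23.1,17.14,0.153785,0.890225,18.184
26.56,11.2762,0.152,0.682856,12.111
30.54,7.41718,0.150014,0.523735,8.09093
33.16,5.79432,0.148744,0.447914,6.39098
33.18,33.55,0.148734,0.447402,34.1461
35.11,28.898,0.147818,0.401832,29.4477
40.37,19.9899,0.145395,0.308213,20.4435
46.42,13.8262,0.142738,0.236387,14.2054
53.37,9.56624,0.139846,0.181342,9.88742
61.36,6.61894,0.136712,0.139117,6.89477
70.55,4.57903,0.13334,0.106713,4.81909
81.11,3.16847,0.12974,0.0818693,3.38008
93.26,2.19185,0.12592,0.0627974,2.38056
107.23,1.51625,0.121901,0.0481683,1.68632
123.28,1.04918,0.11771,0.0369544,1.20384
141.75,0.725746,0.113368,0.0283445,0.867459
162.98,0.502078,0.108912,0.0217424,0.632732
187.38,0.347389,0.104375,0.0166797,0.468444
215.44,0.240339,0.0997886,0.0127951,0.352923
247.71,0.166263,0.0951853,0.00981454,0.271263
284.8,0.115032,0.0905983,0.00752899,0.21316
327.45,0.0795835,0.0860522,0.00577547,0.171411
376.49,0.0550575,0.0815703,0.00443028,0.141058
432.88,0.0380886,0.077171,0.00339832,0.118658
497.7,0.0263519,0.0728702,0.0026069,0.101829
572.24,0.0182305,0.068677,0.0019997,0.0889072
657.93,0.0126128,0.0646007,0.00153399,0.0787475
756.46,0.00872591,0.0606464,0.00117671,0.070549
869.75,0.00603677,0.0568188,0.000902637,0.0637582
1000,0.00417644,0.0531221,0.000692409,0.0579909
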