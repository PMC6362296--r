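"energy_keV","pe","compton","rayleigh","total"
10,25.4087,0.18583,0.635463,26.23
11.5,16.6682,0.184812,0.487264,17.3403
13.22,10.9469,0.183662,0.373895,11.5045
15.2,7.18033,0.182361,0.286805,7.6495
17.48,4.67476,0.180893,0.219918,5.07558
20.09,3.04855,0.179251,0.168822,3.39662
23.1,1.97467,0.177406,0.129487,2.28157
26.56,1.27923,0.175346,0.0993246,1.5539
30.54,0.828128,0.173055,0.0761796,1.07736
35.11,0.534521,0.170521,0.0584482,0.76349
40.37,0.344777,0.167726,0.044831,0.557334
46.42,0.221733,0.164662,0.0343835,0.420779
53.37,0.14258,0.161325,0.026377,0.330282
61.36,0.0916214,0.157711,0.0202352,0.269567
70.55,0.0588407,0.15382,0.0155219,0.228183
81.11,0.0377953,0.149667,0.0119083,0.199371
93.26,0.0242545,0.14526,0.00913416,0.178649
107.23,0.0155799,0.140624,0.0070063,0.16321
123.28,0.0100206,0.135789,0.00537519,0.151185
141.75,0.00644249,0.13078,0.00412284,0.141346
162.98,0.00416951,0.12564,0.00316253,0.132972
187.38,0.00271082,0.120406,0.00242614,0.125543
215.44,0.00177291,0.115115,0.0018611,0.118749
247.71,0.00116551,0.109805,0.00142757,0.112398
284.8,0.000766323,0.104514,0.00109513,0.106375
327.45,0.000517812,0.0992692,0.000840068,0.100627
376.49,0.00035562,0.0940989,0.000644404,0.095099
432.88,0.000248228,0.0890239,0.000494301,0.0897665
497.7,0.000175457,0.0840625,0.000379185,0.0846172
572.24,0.000148574,0.0792252,0.000290865,0.0796647
657.93,0.000118957,0.0745229,0.000223125,0.074865
756.46,9.22445e-05,0.0699612,0.000171158,0.0702246
869.75,8.12767e-05,0.0655458,0.000131293,0.0657584
1000,7.80068e-05,0.0612813,0.000100714,0.06146
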