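"energy_keV","pe","compton","rayleigh","total"
10,27.5965,0.198558,0.714895,28.51
11.5,18.3939,0.19747,0.548172,19.1395
13.22,12.2735,0.196241,0.420632,12.8904
15.2,8.17783,0.194852,0.322656,8.69533
17.48,5.39836,0.193283,0.247408,5.83906
20.09,3.5689,0.191528,0.189924,3.95036
23.1,2.33643,0.189557,0.145673,2.67166
26.56,1.52974,0.187356,0.11174,1.82884
30.54,1.00044,0.184908,0.0857021,1.27105
35.11,0.650346,0.182201,0.0657543,0.898301
40.37,0.422429,0.179215,0.0504349,0.652078
46.42,0.273093,0.17594,0.0386815,0.487714
53.37,0.176298,0.172374,0.0296741,0.378346
61.36,0.113498,0.168513,0.0227646,0.304775
70.55,0.072783,0.164356,0.0174622,0.254601
81.11,0.0466572,0.159918,0.0133968,0.219972
93.26,0.0297344,0.155209,0.0102759,0.19522
107.23,0.0188955,0.150255,0.00788209,0.177033
123.28,0.0119775,0.14509,0.00604709,0.163114
141.75,0.00758915,0.139738,0.00463819,0.151965
162.98,0.00481357,0.134245,0.00355785,0.142617
187.38,0.00305545,0.128653,0.00272941,0.134438
215.44,0.0019102,0.123,0.00209374,0.127004
247.71,0.00117838,0.117326,0.00160602,0.12011
284.8,0.000727052,0.111672,0.00123202,0.113631
327.45,0.000467418,0.106069,0.000945077,0.107481
376.49,0.000307936,0.100544,0.000724955,0.101577
432.88,0.000212279,0.0951215,0.000556089,0.0958898
497.7,0.00015153,0.0898202,0.000426583,0.0903983
572.24,0.000104008,0.0846516,0.000327223,0.0850829
657.93,8.18782e-05,0.0796272,0.000251016,0.0799601
756.46,6.92063e-05,0.0747531,0.000192553,0.0750149
869.75,6.59384e-05,0.0700352,0.000147704,0.0702489
1000,6.80697e-05,0.0654786,0.000113303,0.06566
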