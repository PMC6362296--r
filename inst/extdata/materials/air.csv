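"energy_keV","pe","compton","rayleigh","total"
10,4.52235,0.192542,0.405107,5.12
11.5,2.89303,0.191486,0.310631,3.39515
13.22,1.85297,0.190295,0.238358,2.28162
15.2,1.18503,0.188947,0.182838,1.55682
17.48,0.750736,0.187426,0.140198,1.07836
20.09,0.476336,0.185725,0.107624,0.769685
23.1,0.29808,0.183813,0.0825482,0.564441
26.56,0.186554,0.181679,0.0633194,0.431552
30.54,0.116461,0.179305,0.0485645,0.34433
35.11,0.0716003,0.17668,0.0372608,0.285541
40.37,0.0439348,0.173784,0.0285798,0.246298
46.42,0.0264252,0.170609,0.0219195,0.218953
53.37,0.0156957,0.167151,0.0168153,0.199662
61.36,0.00908994,0.163406,0.0128999,0.185396
70.55,0.00498154,0.159375,0.00989523,0.174252
81.11,0.00268999,0.155072,0.00759152,0.165354
93.26,0.00126481,0.150506,0.00582303,0.157594
107.23,0.000270613,0.145702,0.00446652,0.150439
123.28,2.63994e-05,0.140693,0.00342669,0.144146
141.75,2.57002e-06,0.135503,0.00262831,0.138134
162.98,1e-06,0.130177,0.00201611,0.132194
187.38,1e-06,0.124755,0.00154666,0.126302
215.44,1e-06,0.119273,0.00118645,0.12046
247.71,1e-06,0.113771,0.000910076,0.114682
284.8,1e-06,0.108288,0.000698143,0.108987
327.45,1e-06,0.102854,0.000535543,0.103391
376.49,1e-06,0.0974973,0.000410808,0.0979091
432.88,1e-06,0.092239,0.000315117,0.0925551
497.7,1e-06,0.0870984,0.000241731,0.0873411
572.24,1e-06,0.0820864,0.000185426,0.0822729
657.93,1.87005e-06,0.0772143,0.000142242,0.0773584
756.46,4.82457e-06,0.0724879,0.000109113,0.0726018
869.75,1.06858e-05,0.0679129,8.36991e-05,0.0680073
1000,2.13686e-05,0.0634944,6.42052e-05,0.06358
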