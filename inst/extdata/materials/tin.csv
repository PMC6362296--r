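"energy_keV","pe","compton","rayleigh","total"
10,189.37,0.162455,3.97164,193.504
11.5,124.514,0.161564,3.0454,127.721
13.22,81.9626,0.160559,2.33685,84.46
15.2,53.9237,0.159422,1.79253,55.8756
17.48,35.4557,0.158139,1.37449,36.9883
20.09,23.3545,0.156703,1.05514,24.5663
23.1,15.3629,0.15509,0.809296,16.3273
26.56,10.1071,0.153289,0.620779,10.8812
29.19,7.61391,0.151958,0.51883,8.2847
29.21,41.0349,0.151948,0.518155,41.7051
30.54,36.3867,0.151286,0.476123,37.0141
35.11,24.9704,0.149071,0.365301,25.4848
40.37,17.1289,0.146628,0.280194,17.5558
46.42,11.7486,0.143949,0.214897,12.1074
53.37,8.06096,0.141032,0.164856,8.36685
61.36,5.53094,0.137872,0.12647,5.79528
70.55,3.79444,0.134471,0.097012,4.02592
81.11,2.60368,0.13084,0.0744267,2.80895
93.26,1.78612,0.126988,0.0570885,1.9702
107.23,1.22528,0.122935,0.0437894,1.392
123.28,0.840773,0.118708,0.033595,0.993077
141.75,0.576736,0.11433,0.0257677,0.716833
162.98,0.395664,0.109836,0.0197658,0.525265
187.38,0.271479,0.10526,0.0151634,0.391903
215.44,0.186255,0.100635,0.0116319,0.298522
247.71,0.127774,0.0959928,0.00892231,0.232689
284.8,0.087666,0.0913668,0.00684454,0.185877
327.45,0.0601447,0.0867822,0.00525043,0.152177
376.49,0.0412624,0.0822623,0.00402753,0.127552
432.88,0.0283072,0.0778256,0.00308938,0.109222
497.7,0.0194212,0.0734883,0.00236991,0.0952795
572.24,0.0133238,0.0692595,0.00181791,0.0844012
657.93,0.00914121,0.0651487,0.00139453,0.0756844
756.46,0.00627144,0.0611608,0.00106974,0.068502
869.75,0.00430253,0.0573008,0.000820579,0.0624239
1000,0.00295181,0.0535727,0.000629463,0.057154
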