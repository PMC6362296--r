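"energy_keV","pe","compton","rayleigh","total"
10,840.626,0.155254,7.94328,848.725
11.5,552.725,0.154403,6.0908,558.971
13.22,363.838,0.153442,4.67369,368.666
15.2,239.371,0.152355,3.58507,243.109
17.48,157.391,0.151129,2.74898,160.291
20.09,103.672,0.149757,2.11027,105.932
23.1,68.1973,0.148215,1.61859,69.9641
26.56,44.8661,0.146494,1.24156,46.2542
30.54,29.5118,0.14458,0.952245,30.6086
35.11,19.4227,0.142463,0.730603,20.2958
40.37,12.7769,0.140129,0.560387,13.4774
46.42,8.40403,0.137568,0.429794,8.97139
53.37,5.52982,0.13478,0.329712,5.99432
61.36,3.6387,0.131761,0.25294,4.02341
69.52,2.50192,0.128864,0.199522,2.83031
69.54,11.2494,0.128857,0.199413,11.5777
70.55,10.8199,0.128511,0.194024,11.1424
81.11,7.42443,0.125041,0.148853,7.69832
93.26,5.09315,0.121359,0.114177,5.32868
107.23,3.49389,0.117485,0.0875788,3.69896
123.28,2.39747,0.113446,0.0671899,2.57811
141.75,1.64457,0.109262,0.0515355,1.80536
162.98,1.12824,0.104967,0.0395316,1.27274
187.38,0.774125,0.100594,0.0303267,0.905046
215.44,0.531108,0.0961741,0.0232638,0.650546
247.71,0.364348,0.0917376,0.0178446,0.47393
284.8,0.24998,0.0873168,0.0136891,0.350986
327.45,0.171503,0.0829353,0.0105009,0.264939
376.49,0.11766,0.0786158,0.00805505,0.204331
432.88,0.0807182,0.0743758,0.00617877,0.161273
497.7,0.0553798,0.0702308,0.00473982,0.13035
572.24,0.0379929,0.0661894,0.00363581,0.107818
657.93,0.0260662,0.0622608,0.00278906,0.0911161
756.46,0.0178831,0.0584497,0.00213947,0.0784722
869.75,0.0122687,0.0547608,0.00164116,0.0686707
1000,0.00841712,0.051198,0.00125893,0.060874
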