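"energy_keV","pe","compton","rayleigh","total"
10,214.215,0.176034,1.50922,215.9
11.5,147.932,0.175069,1.15725,149.264
13.22,102.26,0.173979,0.888002,103.322
15.2,70.5651,0.172747,0.681163,71.419
17.48,48.0767,0.171357,0.522306,48.7703
20.09,32.7972,0.169801,0.400951,33.368
23.1,22.1104,0.168053,0.307532,22.586
26.56,14.9074,0.166102,0.235896,15.3094
30.54,10.0365,0.163932,0.180927,10.3814
35.11,6.70226,0.161532,0.138815,7.0026
40.37,4.47215,0.158884,0.106474,4.73751
46.42,2.96913,0.155981,0.0816608,3.20677
53.37,1.96902,0.15282,0.0626454,2.18448
61.36,1.30302,0.149396,0.0480586,1.50048
70.55,0.860214,0.145711,0.0368646,1.04279
81.11,0.567938,0.141777,0.0282821,0.737997
93.26,0.374375,0.137602,0.0216936,0.533671
107.23,0.246965,0.13321,0.01664,0.396815
123.28,0.163087,0.12863,0.0127661,0.304483
141.75,0.107657,0.123886,0.00979174,0.241334
162.98,0.0713018,0.119016,0.00751101,0.197829
187.38,0.0473331,0.114059,0.00576208,0.167154
215.44,0.0316644,0.109047,0.00442011,0.145131
247.71,0.0213257,0.104016,0.00339048,0.128732
284.8,0.0143646,0.0990037,0.00260092,0.115969
327.45,0.00980052,0.0940359,0.00199516,0.105832
376.49,0.00673773,0.0891381,0.00153046,0.0974063
432.88,0.0046858,0.0843307,0.00117397,0.0901905
497.7,0.00328804,0.0796308,0.000900565,0.0838194
572.24,0.00234972,0.0750486,0.000690804,0.0780891
657.93,0.00170816,0.0705941,0.000529922,0.0728322
756.46,0.00125229,0.066273,0.0004065,0.0679317
869.75,0.000941653,0.0620903,0.00031182,0.0633438
1000,0.000720211,0.0580506,0.000239196,0.05901
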