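"energy_keV","csda_g_cm2"
10,0.0002515
20,0.0008566
30,0.001756
40,0.002919
50,0.00432
60,0.005938
80,0.009773
100,0.01431
150,0.02817
200,0.04488
300,0.08421
400,0.128
500,0.1766
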