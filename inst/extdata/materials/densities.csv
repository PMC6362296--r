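"material","density_g_cm3","z_eff"
"water",1,7.42
"air",0.001205,7.64
"bone_cortical",1.85,13.8
"aluminium",2.699,13
"copper",8.96,29
"film_plastic",1.2,7
"tin",7.31,50
"tungsten",19.3,74
"iodine",4.93,53
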