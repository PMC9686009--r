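energy_kev,weight,mu_water_mm,harden_bone,harden_metal
50,0.30,0.0227,1.60,100.0
70,0.35,0.0193,1.15,60.0
90,0.25,0.0176,0.95,45.0
110,0.10,0.0167,0.85,40.0
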