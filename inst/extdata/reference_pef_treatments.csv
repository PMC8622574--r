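sample,pef_treated,cacl2_ppm,pulse_count,pulse_width_us,specific_energy_kj_kg
A,TRUE,0,2000,20,8
B,TRUE,300,900,20,13
C,FALSE,300,0,NA,0
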