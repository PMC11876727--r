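region,factor_Gy_per_MBq_h,mass_g,reference_mass_g
kidney_left,0.00056,150,150
kidney_right,0.00063,135,135
kidney_total,0.0003,285,285
spleen,0.00047,180,180
liver,0.000047,1800,1800
lesion1,0.0056,15,15
lesion2,0.0085,10,10
lesion3,0.007,12,12
lesion4,0.0106,8,8
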