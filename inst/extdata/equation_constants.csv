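name,value,citation
weir_vo2_kcal_per_l,3.941,Weir JB (1949) J Physiol 109:1-9; abbreviated form without urinary nitrogen
weir_vco2_kcal_per_l,1.106,Weir JB (1949) J Physiol 109:1-9; abbreviated form without urinary nitrogen
minutes_per_day,1440,unit conversion
mehta_k_kcal_per_l_co2,5.534,Mehta NM et al. (2015) JPEN 39:566-573; VCO2-based equation
registry_version,1,picuree bundled registry v1
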