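category,period,richness_area_km2,protected_km2,conservation_forest_km2,forest_km2
wide_endemic,current,7235,425,108,1288
narrow_endemic_lowland,current,291,35,13,125
narrow_endemic_montane,current,1326,352,180,615
nonendemic_dry,current,3946,106,93,786
nonendemic_wet,current,4239,250,47,840
wide_endemic,MIROC5-rcp26-2050,6875,7,7,NA
narrow_endemic_lowland,MIROC5-rcp26-2050,356,0.7,0.06,NA
narrow_endemic_montane,MIROC5-rcp26-2050,NA,NA,NA,NA
nonendemic_dry,MIROC5-rcp26-2050,1070,10,8,NA
nonendemic_wet,MIROC5-rcp26-2050,19,0,0,NA
wide_endemic,MIROC5-rcp26-2070,9463,22,22,NA
narrow_endemic_lowland,MIROC5-rcp26-2070,99,0.2,0.09,NA
narrow_endemic_montane,MIROC5-rcp26-2070,NA,NA,NA,NA
nonendemic_dry,MIROC5-rcp26-2070,46,0.9,0.9,NA
nonendemic_wet,MIROC5-rcp26-2070,2059,16,6,NA
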