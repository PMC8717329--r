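species,category,occurrence_points,endemic
M. capitellatum,nonendemic_dry,25,FALSE
M. clarkeanum,nonendemic_wet,47,FALSE
M. cuneatum,narrow_endemic_montane,15,TRUE
M. discolor,narrow_endemic_lowland,18,TRUE
M. fuscescens,narrow_endemic_lowland,17,TRUE
M. grande,nonendemic_wet,25,FALSE
M. hookeri,nonendemic_wet,18,FALSE
M. orbiculare,narrow_endemic_lowland,20,TRUE
M. ovoideum,narrow_endemic_montane,17,TRUE
M. parvifolium,narrow_endemic_montane,16,TRUE
M. petiolatum,nonendemic_dry,21,FALSE
M. procerum,narrow_endemic_lowland,18,TRUE
M. rhinophyllum,wide_endemic,21,TRUE
M. rivulare,narrow_endemic_lowland,35,TRUE
M. rostratum,narrow_endemic_lowland,25,TRUE
M. rotundatum,narrow_endemic_montane,15,TRUE
M. royenii,wide_endemic,20,TRUE
M. sylvaticum,wide_endemic,32,TRUE
M. umbellatum,nonendemic_dry,30,FALSE
M. urceolatum,wide_endemic,20,TRUE
M. varians,narrow_endemic_lowland,31,TRUE
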