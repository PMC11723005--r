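group,kind,cross_type,dbh_cm,height_m,volume_m3,hdr
DxM population,population,DxM,35,25,1.0,0.71
DM-9-17,clone,DxM,42,26,1.4,0.62
DM-9-18,clone,DxM,39,26,1.2,0.65
DM-9-14,clone,DxM,39,25,1.2,0.63
MxD population,population,MxD,32,24,0.8,0.75
MD-61,clone,MxD,38,24,1.2,0.63
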