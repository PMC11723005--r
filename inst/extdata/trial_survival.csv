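clone_id,cross_type,cuttings_planted,cuttings_surviving
DM-9-22,DxM,20,18
DM-9-16,DxM,20,16
DM-9-18,DxM,20,16
DM-9-24,DxM,20,16
DM-9-8,DxM,20,16
DM-9-25,DxM,20,15
DM-9-17,DxM,20,15
DM-9-2,DxM,20,14
DM-9-26,DxM,20,14
DM-9-14,DxM,20,13
DM-9-10,DxM,20,10
DM-9-6,DxM,20,9
DM-9-15,DxM,20,8
DM-9-1,DxM,20,8
DM-9-3,DxM,20,8
MD-19,DxM,20,6
MD-102,MxD,20,17
MD-65,MxD,20,15
MD-66,MxD,20,15
MD-64,MxD,20,14
MD-61,MxD,20,13
MD-46,MxD,20,13
MD-19,MxD,20,12
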