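early_age,cross_type,rp,significance
2,DxM,0.48,ns
3,DxM,0.65,*
4,DxM,0.58,*
5,DxM,0.69,*
6,DxM,0.79,*
7,DxM,0.88,**
8,DxM,0.89,**
9,DxM,0.93,**
10,DxM,0.96,**
11,DxM,0.99,**
12,DxM,0.99,**
13,DxM,1.00,**
2,MxD,0.09,ns
3,MxD,0.48,*
4,MxD,0.61,*
5,MxD,0.71,*
6,MxD,0.77,*
7,MxD,0.85,*
8,MxD,0.87,*
9,MxD,0.86,*
10,MxD,0.95,**
11,MxD,0.98,**
12,MxD,0.98,**
13,MxD,0.99,**
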