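site_id,distance_km,timepoint,metal,concentration,sd
S1,0.6,initial,Hg,22.13,0.57
S1,0.6,initial,Pb,1997.02,2.06
S1,0.6,initial,As,37.52,0.48
S2,3,initial,Hg,5.38,0.72
S2,3,initial,Pb,186.03,3.93
S2,3,initial,As,15.70,0.16
S3,10,initial,Hg,2.05,0.22
S3,10,initial,Pb,57.19,5.72
S3,10,initial,As,7.90,0.74
S1,0.6,final,Pb,1433,46
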