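site_id,harvest_id,metal,value,censored,lod
S2,C1,Hg,0.07,FALSE,0.0001
S2,C1,Pb,0.090,FALSE,0.08
S2,C1,As,,TRUE,0.05
S2,C2,Hg,0.05,FALSE,0.0001
S2,C2,Pb,,TRUE,0.08
S2,C2,As,,TRUE,0.05
S2,C3,Hg,0.100,FALSE,0.0001
S2,C3,Pb,,TRUE,0.08
S2,C3,As,,TRUE,0.05
S2,C4,Hg,0.05,FALSE,0.0001
S2,C4,Pb,,TRUE,0.08
S2,C4,As,,TRUE,0.05
S3,C1,Hg,0.0001,FALSE,0.0001
S3,C1,Pb,,TRUE,0.08
S3,C1,As,,TRUE,0.05
S3,C2,Hg,0.0001,FALSE,0.0001
S3,C2,Pb,,TRUE,0.08
S3,C2,As,,TRUE,0.05
S3,C3,Hg,0.0001,FALSE,0.0001
S3,C3,Pb,,TRUE,0.08
S3,C3,As,,TRUE,0.05
S3,C4,Hg,0.0004,FALSE,0.0001
S3,C4,Pb,,TRUE,0.08
S3,C4,As,,TRUE,0.05
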