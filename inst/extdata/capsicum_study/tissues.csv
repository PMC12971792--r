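plant_id,site_id,organ,metal,value,censored,lod
S1-P,S1,root,Hg,2.29,FALSE,0.0001
S2-P,S2,root,Hg,1.61,FALSE,0.0001
S3-P,S3,root,Hg,0.95,FALSE,0.0001
S1-P,S1,root,Pb,70.6,FALSE,0.08
S2-P,S2,root,Pb,28.3,FALSE,0.08
S3-P,S3,root,Pb,,TRUE,0.08
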