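site_id,metal,schema,fraction_id,percent
S1,Pb,tessier,F1,5.34
S1,Pb,tessier,F2,1.31
S2,Pb,tessier,F1,2.92
S2,Pb,tessier,F2,2.09
S3,Pb,tessier,F1,10.99
S3,Pb,tessier,F2,4.35
S1,Hg,bloom,F1,0.4
S1,Hg,bloom,F2,0.3
S2,Hg,bloom,F1,0.4
S2,Hg,bloom,F2,0.3
S3,Hg,bloom,F1,0.4
S3,Hg,bloom,F2,0.3
S1,As,tessier,F1,0.3
S1,As,tessier,F2,0.4
S2,As,tessier,F1,0.3
S2,As,tessier,F2,0.4
S3,As,tessier,F1,0.3
S3,As,tessier,F2,0.4
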