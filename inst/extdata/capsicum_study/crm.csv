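analyte,certified,certified_u,measured,measured_sd,n_reps
As,0.63,0.08,0.67,0.04,3
Pb,0.117,0.017,0.121,0.010,3
Hg,0.20,0.04,0.21,0.03,3
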