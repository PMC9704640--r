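id,d18O,d18O_sd,d15N,d15N_sd,SP,SP_sd
x1,47.6,0.5,-35.2,1.0,11.1,1.0
x2,26.3,0.5,-45.0,1.0,3.0,1.0
x3,24.8,0.5,-54.0,1.0,31.7,1.0
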