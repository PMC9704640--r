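id,d15N,d15N_sd,d18O,d18O_sd
x1,-8.3,0.5,8.1,0.5
x2,1.2,0.5,12.9,0.5
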