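id,d18O,d18O_sd,d15N,d15N_sd
x1,11.8,2.5,3.2,1.9
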