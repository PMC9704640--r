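name,mode,d15N_mean,d15N_sd,d18O_mean,d18O_sd
River_A,point,5.0,0.5,2.5,0.5
Fertilizer,point,-16.5,0.5,11.2,0.5
Manure,point,3.0,3.0,4.5,0.5
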