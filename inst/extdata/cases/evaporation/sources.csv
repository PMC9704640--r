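name,mode,d18O_mean,d18O_sd,d2H_mean,d2H_sd
Inflow,point,-5.0,0.2,-34,3
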