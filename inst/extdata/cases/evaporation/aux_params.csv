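name,role,d18O_mean,d18O_sd,d2H_mean,d2H_sd
A,humidity-temperature slope,1.7881,0.005,1.5824,0.03
D,limiting enrichment,5.6063,0.005,0.2946,0.03
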