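name,role,d15N_mean,d15N_sd,d18O_mean,d18O_sd
E,fractionation factor,-15.9,2.0,-8.0,2.0
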