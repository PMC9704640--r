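name,role,I1_mean,I1_sd,I2_mean,I2_sd
A,fractionation factor,-5,1,-5,1
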