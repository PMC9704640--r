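id,I1,I1_sd,I2,I2_sd
x1,25,1,25,1
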