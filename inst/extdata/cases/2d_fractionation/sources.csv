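name,mode,I1_mean,I1_halfrange,I2_mean,I2_halfrange
S1,range,0,3,0,4
S2,range,10,4,30,3
S3,range,20,3,0,4
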