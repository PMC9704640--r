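name,mode,I1_mean,I1_halfrange
S1,range,2,2
S2,range,20,4
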