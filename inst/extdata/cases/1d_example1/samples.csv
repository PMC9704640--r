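id,I1,I1_sd
x1,11,0.1
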