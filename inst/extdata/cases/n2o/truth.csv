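id,f_bD,f_nD,f_fD,f_Ni,r
x1,0.9,0.0,0.1,0.0,0.2
x2,0.9,0.0,0.1,0.0,0.8
x3,0.1,0.0,0.0,0.9,0.9
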