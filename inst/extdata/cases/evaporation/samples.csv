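id,d18O,d18O_sd,d2H,d2H_sd
Lakewater,-2.0,0.2,-25,3
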