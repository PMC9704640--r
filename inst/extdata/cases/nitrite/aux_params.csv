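name,role,d18O_mean,d18O_sd,d15N_mean,d15N_sd
A,nitrite reduction fractionation,-4.0,2.0,-10.0,2.0
B,nitrite oxidation fractionation,5.0,2.0,13.0,2.0
C,oxygen equilibrated fraction,0.25,0.01,0.00,0.00
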