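name,d15N_NH4,d15N_NH4_sd,eps_nit,eps_nit_sd,d18O_H2O,d18O_H2O_sd,d18O_O2
Fertilizer,0.5,0.5,-17.0,6.5,5.0,5.0,23.5
Manure,20.0,3.0,-17.0,6.5,-5.0,0.5,23.5
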