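name,role,d18O_mean,d18O_sd,d15N_mean,d15N_sd,SP_mean,SP_sd
A,reduction fractionation,-15.4,4.7,-7.1,2.1,-5.9,1.4
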