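name,d18O_from,d18O_to,d15N_from,d15N_to,SP_from,SP_to
bD,17.8,20.6,-52.8,-42.4,-5.2,0.4
nD,14.4,17.4,-60.7,-53.1,-7.0,2.8
fD,43.4,51.0,-44.4,-31.2,31.0,36.0
Ni,21.4,25.6,-63.9,-49.3,32.0,36.0
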