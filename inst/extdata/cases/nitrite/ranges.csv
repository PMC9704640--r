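name,d18O_from,d18O_to,d15N_from,d15N_to
NAR,3.3,5.3,-14.3,-12.3
AOX,16.4,20.4,65.9,71.9
ORG,16.4,20.4,4.4,6.4
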