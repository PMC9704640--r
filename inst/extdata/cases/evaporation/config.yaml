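sources: sources.csv
samples: samples.csv
aux_params: aux_params.csv
equation: craig_gordon
aux_vars: [r]
note: >
  Single-source Craig-Gordon evaporation model for lake water; r is the
  evaporation-to-inflow flux ratio (E/I) estimated jointly from d18O and
  d2H.
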