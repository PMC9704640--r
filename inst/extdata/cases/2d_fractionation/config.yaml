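sources: sources.csv
samples: samples.csv
aux_params: aux_params.csv
equation: rayleigh
aux_vars: [r]
note: >
  Post-mixing closed-system (Rayleigh) fractionation on top of the
  three-source 2D mixture; r is the residual unreacted fraction.
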