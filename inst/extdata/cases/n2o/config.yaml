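ranges: ranges.csv
samples: samples.csv
aux_params: aux_params.csv
equation: n2o
aux_vars: [r]
note: >
  N2O from four production pathways (bacterial denitrification bD,
  nitrifier denitrification nD, fungal denitrification fD, nitrification
  Ni) with Rayleigh fractionation during partial reduction to N2; r is the
  residual unreduced fraction. Source ranges are stored as printed from/to
  bounds; midpoints are derived on load. truth.csv lists the pathway
  contributions and r used to construct the synthetic samples. Note:
  forward evaluation of the range midpoints reproduces the samples' d15N
  exactly but differs by up to ~0.9 permil for d18O and SP; the samples are
  stored verbatim, not adjusted.
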