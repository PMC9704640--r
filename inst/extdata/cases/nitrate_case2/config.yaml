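sources: sources.csv
samples: samples.csv
aux_params: aux_params.csv
equation: open_system_reduced
aux_vars: [r]
note: >
  As nitrate_case1 but allowing open-system denitrification of the mixed
  nitrate pool: mu = sum f_i S_i - E r with r the reduced-nitrate fraction
  and E the denitrification fractionation factor.
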