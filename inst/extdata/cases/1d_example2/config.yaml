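sources: sources.csv
samples: samples.csv
equation: mixing
note: >
  Same mixture as 1d_example1 but with the sources defined as uniform
  ranges; the posterior is a smoothed plateau over the feasible interval
  f1 in (0.3125, 0.65).
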