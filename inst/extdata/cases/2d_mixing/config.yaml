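sources: sources.csv
samples: samples.csv
equation: mixing
note: >
  Three well-separated range-mode sources on two signatures; the sample sits
  at the centroid, so every true fraction is 1/3.
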