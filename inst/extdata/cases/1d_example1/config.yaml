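sources: sources.csv
samples: samples.csv
equation: mixing
note: >
  Two point-mode sources on one signature; equal true contributions
  (f1 = f2 = 0.5).
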