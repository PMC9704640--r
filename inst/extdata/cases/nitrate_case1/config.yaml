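sources: sources.csv
samples: samples.csv
equation: mixing
note: >
  River nitrate at an agricultural site as a mixture of upstream river
  nitrate, nitrified fertilizer ammonium and nitrified manure ammonium.
  The fertilizer and manure end-members are recalculated from the measured
  ammonium d15N and the local water d18O (measured.csv) via the
  nitrification recalculation (d15N + eps; 2:1 water:O2 oxygen budget).
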