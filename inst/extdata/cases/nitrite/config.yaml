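ranges: ranges.csv
samples: samples.csv
aux_params: aux_params.csv
equation: nitrite
equil_value: 8.6
note: >
  Soil nitrite formed by nitrate reduction (NAR), ammonium oxidation (AOX)
  and organic-N oxidation (ORG), consumed by nitrite reduction and nitrite
  oxidation in a fixed 0.7:0.3 ratio (open system), with a known fraction C
  of the nitrite oxygen equilibrated with soil water (equilibrated value
  +8.6 permil). Source ranges are stored as printed from/to bounds;
  midpoints and half-ranges are derived on load.
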