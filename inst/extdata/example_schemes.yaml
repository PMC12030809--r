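# Example user-defined sampling schemes for load_schemes().
# Hours are since the 06:00 admission start; max_degree must stay
# below the number of grid points.
MORN4:
  hours: [0, 2, 4, 24]
  max_degree: 2
CLINIC6:
  hours: [0, 3, 6, 10, 16, 24]
  max_degree: 3
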