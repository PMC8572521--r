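scenario: fig3_ptl
strategy: ptl
params:
  N0: 2.0
simulation:
  t_end: 2400
  transient_fraction: 0.8
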