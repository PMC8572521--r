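scenario: s6_ptw_r_high
strategy: ptw
params:
  r: 1
analysis:
  N0_grid: {from: 0.6, to: 30.0, length: 60, log: false}
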