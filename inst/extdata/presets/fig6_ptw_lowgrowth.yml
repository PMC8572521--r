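scenario: fig6_ptw_lowgrowth
strategy: ptw
params:
  y1: 3.75
  y2: 2
simulation:
  output_step: 2
analysis:
  N0_grid: {from: 0.6, to: 8.0, length: 25, log: false}
  sweep_axis: period
  axis_grid: {from: 24.0, to: 8760.0, length: 25, log: true}
  fixed_a: 0.9
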