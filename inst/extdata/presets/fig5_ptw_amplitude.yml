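scenario: fig5_ptw_amplitude
strategy: ptw
simulation:
  output_step: 2
analysis:
  N0_grid: {from: 0.6, to: 8.0, length: 25, log: false}
  sweep_axis: amplitude
  axis_grid: {from: 0.0, to: 0.99, length: 25, log: false}
  fixed_T_h: 720.0
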