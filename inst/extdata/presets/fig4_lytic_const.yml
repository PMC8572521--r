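scenario: fig4_lytic_const
strategy: lytic
analysis:
  N0_grid: {from: 0.6, to: 30.0, length: 60, log: false}
  fluctuating: false
  bif_a: 0.5
  bif_T_h: 168.0
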