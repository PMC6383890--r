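# Plausible three-pool configuration for mouse brain at 9.4 T.
# These are documented defaults, not values measured by any one study.
scanner:
  field_strength: 9.4
  gamma_bar: 42.577
pulses:
  cest:  {b1: 0.9, duration: 1.6}
  wassr: {b1: 0.1, duration: 0.5}
pools:
  - {name: water,          t1: 1.8, t2: 0.040, shift:  0.0, fraction: 1.0,   k_exchange: 0}
  - {name: hydroxyl,       t1: 1.0, t2: 0.015, shift:  0.6, fraction: 0.002, k_exchange: 600}
  - {name: macromolecular, t1: 1.0, t2: 0.0005, shift: -2.4, fraction: 0.005, k_exchange: 30}
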