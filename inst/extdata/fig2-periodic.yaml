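oscillator:
  damping_p: 0.2
  stiffness_q: 0.3
  restitution_alpha: 0.8
  wall_x0: 0.2
forcing:
  variant: periodic
  amplitude: 1.0
  angular_frequency: 1.0
  t_on: 6.283185307179586
  t_off: 62.83185307179586
initial:
  x: 0.0
  v: 0.0
  t: 0.0
solver:
  t_end: 94.24777960769379
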