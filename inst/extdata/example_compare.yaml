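# Hegar (near-step) versus CCBD (45-s ramp) on the same coarse mesh.
geometry:
  n_radial: 6
  n_circumferential: 12
material:
  E: 0.15 MPa
  nu: 0.3
  k_perm: 3.0e-15
solver:
  dt: 0.5
  t_end: 60
protocols:
  - kind: ramp
    p_max: 10 kPa
    t_rise: 1
    label: Hegar near-step
  - kind: ramp
    p_max: 10 kPa
    t_rise: 45
    label: CCBD ramp
bc:
  preset: compliant
output:
  snapshot_times: [5, 20, 35, 45]
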