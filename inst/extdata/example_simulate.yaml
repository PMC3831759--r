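# Hydraulic balloon dilation of the cervical canal (coarse demo mesh).
geometry:
  r_inner: 1.5e-3
  r_outer: 10.0e-3
  n_radial: 6
  n_circumferential: 12
  half_model: true
material:
  E: 0.15 MPa
  nu: 0.3
  k_perm: 3.0e-15
solver:
  dt: 0.5
  t_end: 60
protocol:
  kind: ramp
  p_max: 10 kPa
  t_rise: 45
  label: CCBD ramp
bc:
  preset: default
output:
  formats: [vtk, csv, json]
  snapshot_times: [5, 20, 35, 45]
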