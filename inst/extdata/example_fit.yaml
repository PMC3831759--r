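# Recover (E, k) from a synthetic noise-free calibration series.
geometry:
  n_radial: 8
  n_circumferential: 16
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
  preset: calibration
fit:
  synthesis:
    E_true: 0.15 MPa
    k_true: 3.0e-15
    noise_sd: 0
    seed: 1
  initial_E: 0.5 MPa
  initial_k: 1.0e-14
  max_eval: 200
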