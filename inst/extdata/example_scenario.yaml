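# Example insertion scenario for the `endorod` CLI and read_scenario()
dt: 0.001
duration: 5
seed: 1
instrument:
  name: guidewire_standard_035
  total_length_mm: 255
  n_points: 256
  E_b_Pa: 5.0e+6
  radius_mm: 0.4
  density_kg_m3: 8.0e+6
  K_p: 0.2
  alpha: 0.5
  tip_points: 5
  mu: 0.3
solver:
  distance_mode: global_tridiagonal
  outer_iterations: 1
  contact_iterations: 10
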