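# Example run configuration: posterior-median parameters, default anatomy.
parameters:
  a_min: 4.16
  a_max: 93.24
  alpha_L: 0.767
  k_i: 1430
  k_d: 541
  Vc_max: 99.3
  J_max: 186.4
  R_d: 0.14
  alpha: 0.183
  S_e: 8.486e-6
  S_a: 0.280e-6
  g_m: 0.2
leaf_constants:
  SD: 400
  l: 5.89
  leaf_thickness: 200
  airspace_fraction: 0.255
  g_b: 9.29
  P_a: 101.8
environment:
  Ca: 400
  T_leaf: 25
solver:
  atol: 0.01
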