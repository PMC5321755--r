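domain:
  L: 0.013
  H: 0.0013
  Ny: 20.0
  catalytic_interval:
  - 0.00065
  - 0.013
  dz: 'NULL'
consts:
  rho0: 1000.0
  nu: 1.0e-06
  g: 9.800000000000001
  T_amb: 298.0
  kB: 1.380649e-23
reagent:
  D: 1.0e-09
  beta_C: 0.01
  C0: 0.1
  lam: 0.000238095238095
  KM: 0.093
  M_sites: 4.0
  kcat: 212000.0
  E_areal: 2.0e-08
  rmax: 1.7e-05
tracer:
  R: 2.0e-06
  rho_t: 1050.0
  eps: 1.2e-14
  omega: 60000.0
bc:
  family: A
  q0: 'NULL'
numerics:
  tau: 1.35
  n_couple: 100
  out_every: 20
run:
  seed: 1
  'N': 500
  time_scale: 20.0
  horizon: 'NULL'
  noise: yes
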