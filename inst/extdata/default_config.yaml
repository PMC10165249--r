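# Default run configuration: two-guild counter-diffusional biofilm model of
# nitrification in a membrane-aerated reactor, plus the batch-analysis and
# synthetic-campaign settings.  Units: m, d, g/m3, g COD/m3, degC.
schema_version: 1
seed: 1
output_dir: results
log_level: info
params:
  mu_max_AOO: 0.9
  mu_max_NOO: 0.7
  K_NH4: 1.0
  K_NO2: 0.5
  K_O2_AOO: 0.5
  K_O2_NOO: 0.68
  Y_AOO: 0.15
  Y_NOO: 0.041
  b_AOO: 0.05
  b_NOO: 0.05
  i_N: 0.07
  f_I: 0.1
  rho_X: 50000
  T_ref: 20
temperature_rules:
  theta_mu_AOO: 1.095
  theta_mu_NOO: 1.06
  theta_b: 1.04
  henry_ref: 42.8
  henry_vant_hoff_K: 1700
  D_ref:              # aqueous diffusivities at T_ref, m2/d
    O2: 1.710720e-04
    NH4: 1.555200e-04
    NO2: 1.468800e-04
    NO3: 1.468800e-04
  biofilm_diffusivity_ratio: 0.8
  perm_ref: 3.2
  perm_activation_energy: 8400
  T_ref: 20
geometry:
  mode: cylindrical
  Lf: 50.0e-6
  L_LBL: 50.0e-6
  membrane_outer_radius: 275.0e-6
  membrane_wall: 135.0e-6
matrix:
  temperatures: [8, 30]
  Lf: [50.0e-6, 150.0e-6]
  L_LBL: [50.0e-6, 250.0e-6]
  bulk_NH4: 35
  mode: cylindrical
batch:
  windows: [[10, 20], [2.5, 10]]
  T0: 20
  volume_m3: 0.1
  area_m2: 3.74
synthetic:
  temperatures: [30, 24, 18, 12, 8]
  R_T0: 4.0
  theta: 1.026
  T0: 20
  C0: 50
  interval_min: 15
  volume: 0.1
  area: 3.74
  noise_sd: 0.2
  K_app: 1.0
  C_stop: 1.0
  seed: 1
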