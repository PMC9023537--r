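# Demonstration run: synthetic shelf domain with known occurrence truth.
# A step is a monthly mean (period 12); 204 steps = 17 years of months.
seed: 42

grid:
  cell_km: 10
  nx: 18
  ny: 30
  lat0: 25

environment:
  n_steps: 204
  period: 12
  sst_south: 26        # deg C annual mean at the southern edge
  ns_gradient: 1.2     # deg C per 100 km northward
  amplitude: 4         # seasonal half-range, deg C
  peak_step: 7         # July peak
  front_x_km: 65
  front_contrast: 2
  noise_sd: 0.3
  depth_max: 3000
  shelf_exp: 1.8

truth:
  intercept: 0.5
  sst_opt: 23          # thermal optimum, deg C
  sst_width: 3
  betas:
    front_z: 1.5
    dshore_km: -0.015

surveys:
  alpha:               # dual-team survey, hazard-rate truth
    teams: [forward, aft]
    steps_from: 1
    steps_to: 36
    spacing_km: 30
    record_interval_s: 40
    strip_m: 600
    density_per_km2: 0.12
    detection:
      key: hr
      sigma_m: 130
      shape: 2.5
      p0: {forward: 0.8, aft: 0.7}
    key_candidates: [hr, hn]
    mr_formula: "~ distance_m * observer"
  bravo:               # single-team survey, half-normal truth
    teams: [forward]
    steps_from: 1
    steps_to: 24
    spacing_km: 40
    record_interval_s: 40
    strip_m: 600
    density_per_km2: 0.12
    detection:
      key: hn
      sigma_m: 150
      p0: {forward: 0.9}
    key_candidates: [hn, hr]

preprocess:
  left_m: 3.2
  right_m: 300
  max_beaufort: 4
  max_altitude_m: 366
  max_heading_change_deg: 20
  dt_max: 15
  dangle_max: 15

detection:
  n_min: 20
  bootstrap_B: 40

sdm:
  pool: [sst, front_z, dshore_km, chla]
  rho_max: 0.7
  interaction: [front_z, sst]
  depth_limit_m: 1835
  cv_k: 10

validation:
  n_independent: 300
  mode: median_ratio

trends:
  order: [1, 1, 1]
  seasonal: [0, 1, 1]
  period: 12
  horizon: 60
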