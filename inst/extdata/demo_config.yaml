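# Demonstration calibration protocol at full scale.
# Scaled-down analogues of this protocol are used in the package tests;
# see the methods vignette for the rationale.
model: negative_feedback.mdl
models:
  - negative_feedback.mdl
  - positive_feedback.mdl
  - feed_forward.mdl
data: demo_data.csv
observation_map:
  X_obs: {species: X, scale_factor: 100}
  Y_obs: {species: Y, scale_factor: 100}
free_parameters:
  - {name: k1, lower: 1.0e-7, upper: 1.0e+4}
  - {name: k2, lower: 1.0e-7, upper: 1.0e+4}
  - {name: k3, lower: 1.0e-7, upper: 1.0e+4}
weighting: sd
n_runs: 300
optimizer:
  algorithm: genetic
  population_size: 300
  generations: 500
chaser:
  algorithm: hooke_jeeves
  top_k: 3
  tolerance: 1.0e-10
  iteration_limit: 1000
profile:
  algorithm: hooke_jeeves
  tolerance: 1.0e-6
  iteration_limit: 50
  span_orders: 3
  n_points: 20
  alpha: 0.95
  interpolation: cubic_spline
truncation:
  mode: fraction
  value: 0.10
selection:
  criterion: aicc
generate:
  times: [0, 1, 2, 4, 8, 12]
  replicates: 6
  noise: gaussian_cv
  cv: 0.1
  protein_rule:
    lag: 0.5
    magnitude: 100
seed: 1
max_workers: 1
output_dir: odecal_runs
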