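# odecal

Calibration, identifiability analysis and model selection for deterministic
kinetic models of biochemical networks, in R.

Systems-biology ODE models — signalling cascades, gene-regulatory motifs,
metabolic modules — must be fitted to sparse, noisy, arbitrary-unit
time-course data before they predict anything. odecal packages the full
calibration workflow for that situation:

- **Models** written in a plain-text reaction language
  (`parse_model()`), compiled to `dx/dt = N v(x, p)` and integrated with a
  stiff-capable adaptive solver (deSolve); SBML L3V1 export/import.
- **Data** as replicated time-course tables in arbitrary units, linked to
  model units by the observation function `X_obs(t) = X(t) / X_SF`; raw
  qPCR Ct tables enter via 2^-ddCt normalization against the geometric mean
  of reference genes (`ddct_normalize()`).
- **Estimation** by minimizing the sd-weighted residual sum of squares

  ```
  RSS(p) = sum_{t,o,r} ( (y_tor - X_o(t;p)/X_SF,o) / sigma_to )^2
  ```

  with multi-start genetic-algorithm searches in log10-parameter space
  (`calibrate()`), refined by Hooke–Jeeves "chaser" estimations
  (`chaser()`), collected in ranked archives with `coef()`, `predict()`,
  `residuals()`, `summary()` and `plot()` methods.
- **Identifiability** by profile likelihood (`profile_likelihood()`,
  `profile_all()`): each parameter fixed along a log-spaced scan, all
  others re-optimized, the curve compared to the likelihood-ratio threshold
  `RSS* + qchisq(0.95, 1)` and classified as identifiable / practically /
  structurally non-identifiable, with co-parameter traces for model
  reduction.
- **Model selection** by small-sample corrected AICc and BIC over archives
  of competing topologies (`multi_model_fit()`, `select_models()`).
- **Diagnostics**: likelihood-ranks (waterfall) plots, bootstrap ensemble
  time courses, parameter box plots/histograms and log-log Pearson
  correlation maps, all exposing their plot-ready numbers.
- **Synthetic fixtures** (`motif_models()`, `smad_demo_models()`,
  `generate_data()`) emulating a 6-time-point, 6-replicate qPCR study
  design, so every stage runs self-contained.

A thin command-line front-end (`exec/odecal`, or `run_pipeline()` from R)
drives the same workflow from YAML configurations into timestamped,
reproducible output directories.

## Worked example

Calibrate the bundled negative-feedback motif against synthetic data
generated from itself (true parameters `k1 = 4, k2 = 0.8, k3 = 0.4`,
10% measurement noise), then profile one parameter:

```r
library(odecal)
mods <- motif_models()
map  <- motif_observation_map()            # X_obs, Y_obs with X_SF = 100
dat  <- generate_data(mods$negative_feedback, noise = "gaussian_cv",
                      cv = 0.1, map = map, seed = 1)

prob <- fit_problem(mods$negative_feedback, dat, map,
                    free = c("k1", "k2", "k3"))   # bounds 1e-7 .. 1e4
fit  <- calibrate(prob, n_runs = 5,
                  config = optimizer_config(population_size = 24,
                                            generations = 40), seed = 1)
fit  <- chaser(fit, top_k = 3)             # Hooke-Jeeves refinement
fit
#> Estimation archive: 8 parameter sets (3 chased), model 'negative_feedback', ranked
#> RSS: best 51.2984, median 269.805, worst 6836.77
coef(fit)
#>        k1        k2        k3
#> 4.0879594 0.7970373 0.3909985
```

The best RSS of 51.3 is an excellent fit for 72 sd-weighted replicate
points, and the chased optimum recovers the generating parameters to a few
percent despite the noise. Profiling `k1` from the best set:

```r
cv  <- profile_likelihood(prob, get_parameter_set(fit, 1), "k1",
                          span_orders = 2, n_points = 8)
thr <- confidence_threshold(cv$best_rss, alpha = 0.95)
classify_profile(cv, thr)
#> $classification
#> [1] "identifiable"
#> $ci_lower
#> [1] 3.673331
#> $ci_upper
#> [1] 4.54652
```

`k1` is identifiable with a 95% profile confidence interval of
[3.67, 4.55], bracketing the true value 4. `plot(likelihood_ranks(fit))`,
`plot(ensemble_timecourse(fit))` and `plot_profiles()` render the standard
diagnostic figures; `select_models(multi_model_fit(...))` ranks competing
topologies by AICc.

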