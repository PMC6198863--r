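---
title: "Calibrating kinetic ODE models with odecal: methods and design"
author: "odecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating kinetic ODE models with odecal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odecal)
```

## The problem

Deterministic kinetic models of signalling networks — systems of ordinary
differential equations derived from reaction networks — only become
predictive after calibration against time-course data. Calibration in this
setting is hard for well-understood reasons: objective landscapes are
multimodal, parameters range over many decades, data are sparse (a handful
of time points, a handful of replicates, in arbitrary measurement units),
and many parameters are simply not determined by the data at all. odecal
implements a complete workflow for this situation: multi-start global
optimization with local "chaser" refinement, profile-likelihood
identifiability analysis, information-criterion model selection, and a set
of ensemble diagnostics for judging whether an optimization can be trusted.

## Models and observation

Models are written in a small plain-text reaction language
(`parse_model()`): species with initial amounts, `const` species fixed as
boundary conditions (input stimuli such as a growth-factor dose), kinetic
parameters and reactions `name: reactants -> products ; rate`. Rate
expressions are arithmetic over `+ - * / ^` and `exp`. The package works in
a single compartment of size one, so amounts and concentrations coincide.
Stoichiometry and rates compile to $\dot{x} = N\,v(x, p)$ and are integrated
with deSolve's `lsoda`, an adaptive stiff-capable (Adams/BDF-switching)
solver. Reporting simulations default to `rtol = 1e-8`, `atol = 1e-10`;
estimation objectives default to `rtol = 1e-6`, `atol = 1e-8` with a 2000
internal-step cap, which keeps tolerancing error orders of magnitude below
replicate noise while letting pathological parameter sets fail fast (a
failed integration scores `+Inf` rather than raising, so stochastic search
continues). Models export to SBML Level 3 Version 1 (`write_sbml()`).

Measurements live in arbitrary units and are linked to model units by the
linear observation function
$$X_{\mathrm{Obs}}(t) = X(t) / X_{SF},$$
one scale factor per observable (`observation_map()`, default
$X_{SF} = 100$). Initial amounts can be tied to data baselines by
$X(t_0) = \bar{X}(t_0)\cdot X_{SF}$ (`set_scaled_initials()`).

qPCR tables enter through the comparative-Ct transform
(`ddct_normalize()`): per sample, target Ct minus the arithmetic mean Ct of
the reference genes (equivalent to normalizing by the geometric mean of
reference expression on the linear scale), then minus the mean $\Delta$Ct
of the calibrator samples, then $2^{-\Delta\Delta C_T}$. The calibrator
defaults to all baseline-time samples, matching the
fold-change-from-baseline presentation such data usually get; the rule is a
plain function argument and can be replaced. Missing values are dropped
pointwise, never imputed; amplification-efficiency and plate effects are
out of scope.

## The objective

The estimation objective is the weighted residual sum of squares over every
replicate data point,
$$\mathrm{RSS}(p) = \sum_{t,o,r}
  \left(\frac{y_{tor} - X_o(t;p)/X_{SF,o}}{\sigma_{to}}\right)^2 ,$$
with $\sigma_{to}$ the sample standard deviation of the replicates at that
time and observable. Two design choices deserve note. First, residuals are
computed against each replicate rather than against replicate means; this
makes the data-point count $n$ used by the information criteria equal the
number of measured values, keeping the weighting and the selection criteria
consistent. Second, standard deviations are floored at 5% of the
observable's grand mean (`sd_floor_frac`), because coinciding replicates —
guaranteed in noise-free synthetic data — would otherwise produce infinite
weights. With a single replicate no sd can be formed and the package
directs you to unweighted mode instead of silently weighting by zero.

## Optimization

Parameters are bounded in $[10^{-7}, 10^{4}]$ by default, eleven decades,
so all search happens in $\log_{10}$ space: starts are log-uniform
(`sample_start()`), the genetic algorithm mutates in decades and
Hooke-Jeeves steps in decades. Linear-space search over such bounds is
hopeless and was never considered.

`calibrate()` (alias `repeat_estimation()`) runs $n$ independent
estimations with seeds `seed + i`; each run owns its RNG stream, so results
are identical whatever the worker count (`max_workers` schedules runs over
forked workers where available). The default global optimizer is a
real-coded genetic algorithm: tournament selection of size 2, uniform
crossover applied with probability 0.5, per-gene Gaussian mutation with
probability $1/d$ and standard deviation 0.2 decades, elitism of one.
These operator choices are standard for real-coded GAs; the convergence
tests (bounded quadratic, parameter recovery) are the contract, and any
operator set passing them would be acceptable. The full-scale protocol in
the bundled demo configuration uses a population of 300 over 500
generations and 300 repeats per model.

"Chaser" estimations (`chaser()`) refine the best global candidates with a
bound-clipped Hooke-Jeeves pattern search (exploratory probes of one step
per coordinate, pattern extrapolation, step halving on failure),
terminating when the step drops below `tolerance` decades or at the
iteration limit. The demo protocol chases the top three sets at tolerance
1e-10 with limit 1000. Pattern search never accepts a worse point, so a
chased RSS is never above its source — a property the tests assert rather
than assume.

## Identifiability by profile likelihood

`profile_likelihood()` fixes one parameter on a log-spaced grid spanning
three decades either side of its best value (intersected with the bounds)
and re-optimizes all remaining parameters at each point with Hooke-Jeeves
(tolerance 1e-6, limit 50 in the demo protocol). The scan sweeps outward
from the optimum in both directions and warm-starts each re-optimization
from its neighbour's solution; warm starting is what makes 40-point
profiles affordable and smooth. The default grid density is 20 points per
direction; tests use coarser scans, which the spline interpolation below
tolerates well (halving the density moves interpolated crossings by under
2% in the refinement tests).

The curve is compared against a likelihood-ratio threshold
(`confidence_threshold()`). The default is the pointwise $\chi^2_1$ form,
$\mathrm{RSS}^* + Q_{\chi^2_1}(\alpha)$ at $\alpha = 0.95$, valid when the
weights are true error scales; an F-based alternative
$\mathrm{RSS}^*(1 + Q_{F_{1,n-p}}(\alpha)/(n-p))$ is provided for the case
where the error scale is estimated, and converges to the $\chi^2$ offset as
$n$ grows. Crossings are located on a cubic-spline interpolation of RSS
against $\log_{10}$ value. Classification follows the standard three-way
rule: crossings on both sides give an identifiable parameter whose
crossings are its confidence bounds; a crossing on one side only (or
neither) marks practical non-identifiability with the uncrossed bounds
infinite; a profile flat to within `flatness_tol` (1e-3 relative) marks
structural non-identifiability. Because a scan only samples the space,
structural calls are reported as *suspected* and should be examined with
co-parameter traces (`coparameter_trace()`), where a compensatory product
coupling $k_1 k_2 = c$ appears as a log-log line of slope $-1$. Profile
likelihood is a local method; `profile_all()` therefore runs the analysis
from several top (chased) parameter sets and flags parameters whose
classification is discordant across starting sets. The chi-squared CI
coverage is verified empirically in the test suite: on a one-parameter
exponential model with known noise, 95% profile intervals cover the truth
at the nominal rate within binomial tolerance over 200 repetitions.

## Model selection

`aicc()` and `bic()` use the RSS-based Gaussian forms
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$,
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$ and
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$, with $n$ the count of
non-missing replicate points and $k$ the number of *estimated* parameters
only (fixed parameters carried over from a published model do not count).
Computing the criteria from the sd-weighted RSS assumes the replicate
standard deviations are the true error scales — a caveat, not a theorem.
`multi_model_fit()` calibrates each candidate against the same data with
the base seed offset by model index; `select_models()` ranks by best
criterion and reports per-set distributions for violin-style comparison.
Models that cannot support the AICc correction ($n \le k+1$) are flagged
and excluded from AICc ranking rather than silently scored.

## Diagnostics

All plotting operations are pure functions of their numeric inputs and
return those numbers for testing; figures are base graphics rendered to
PNG/SVG by `render_figure()`. The likelihood-ranks (waterfall) plot shows
sorted RSS against rank — plateaus mark repeatedly-found minima, smooth
curves mark non-convergence. `ensemble_timecourse()` inserts the top sets
(default 10) into the model and bootstraps an estimator (default the mean,
1000 percentile resamples) per time point, propagating parameter
uncertainty into a prediction band; the simple per-set average is the
degenerate case of the same machinery. Box plots, histograms and Pearson
log-log correlation heat maps (`param_distributions()`,
`param_correlations()`, flag threshold $|r| \ge 0.9$) operate on the
archive after truncation — the top-10% truncation of the demo protocol
exists because sub-optimal sets demonstrably distort these summaries.

## Synthetic fixtures and what they do not show

`motif_models()` provides negative-feedback, positive-feedback and
feed-forward two-state motifs sharing a stimulus, state names, parameter
names and one observation map, so a single fit specification runs against
all three; only the regulatory topology differs. The negative-feedback
motif overshoots and adapts under a step input; the generator's default
study design — sampling at 0, 1, 2, 4, 8, 12 h with 6 replicates, scale
factors of 100, Gaussian noise with a coefficient of variation of 0.1
floored at zero — mirrors the transient such designs are built to capture.
`smad_demo_models()` gives three reduced variants of a Smad7/Ski negative
feedback (driver-induced transcription, saturable Ski inhibition carrying
`km` and `I50`, Smad7-mediated driver degradation that is catalytic,
consuming, or consuming with second-order Ski decay). True parameter values
are fixed constants so tests are stable. Derived protein observables follow
the lag rule $\mathrm{protein}(t) = 100\cdot\mathrm{mRNA}(t - 0.5\,h)$,
holding the baseline before the lag; noise on derived profiles is optional
because the rule is an assumption about reporting, not biology.

These fixtures emulate the *design* of a real calibration study, not real
data: noise is homoscedastic in relative terms, replicates are exchangeable,
there are no batch effects, no amplification-efficiency drift in the
synthesized Ct values, and the generating model is always in the candidate
set. Passing tests therefore demonstrate that the machinery is correct and
that the workflow discriminates topologies *under its own assumptions*;
they say nothing about model adequacy for any particular experimental
system.

## Numerical choices and scales used in testing

Scan grids, population sizes and repeat counts in the test-suite and in
`scripts/acceptance.R` are scaled-down versions of the demo protocol,
chosen once: recovery uses 20 repeats of a 24x40 GA plus a top-3 chase;
topology recovery uses 20 seeded repetitions of a 16x20 GA with a single
run per model and a one-set chase (the chaser, not the GA, supplies
convergence at this scale); profiles in tests use 8 points per direction.
Degenerate inputs are handled explicitly: zero-length simulations return
initial amounts, rank ties break by run id, truncation never returns an
empty archive except under an RSS cutoff, zero-variance parameters are
masked from correlation matrices, and an RSS of exactly zero maps to a
`-Inf` information criterion with a warning.

## Limitations

Deterministic mass-action-style kinetics only — no events, rules, delays,
or stochastic/hybrid simulation. The reaction language is deliberately
minimal. Identifiability analysis is the sampled profile-likelihood method:
it cannot prove structural results, only suggest them. The information
criteria inherit the Gaussian-RSS assumptions above. The worker pool is a
single-machine fork pool; cluster schedulers are out of scope.
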