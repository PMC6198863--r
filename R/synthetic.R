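#' Three regulatory-motif fixture models
#'
#' Small two-state models sharing an input stimulus `S` (a fixed species,
#' representing e.g. a TGF-beta dose switched on at t = 0) and the species
#' `X` (fast responder) and `Y` (downstream output), differing only in the
#' regulatory topology:
#' \describe{
#'   \item{negative_feedback}{`Y` inhibits production of `X`
#'     (`k1*S/(1 + Y/ki)`), giving the classic overshoot-then-adapt response.}
#'   \item{positive_feedback}{`Y` amplifies production of `X` through a
#'     saturable term (`k1*S*(0.1 + Y)/(ki + Y)`), giving a monotone
#'     sigmoid rise without overshoot.}
#'   \item{feed_forward}{`S` drives `X`, and `S` and `X` jointly drive `Y`
#'     (coherent feed-forward), with no feedback.}
#' }
#' All three expose the same parameter names `k1, k2, k3` (the conventional
#' free set) plus `k4` and, where used, `ki`, so that one observation map and
#' one free-parameter specification fit all. True values are fixed constants
#' so that synthetic-data tests are stable.
#'
#' @return a named list of three [kinetic_model] objects.
#' @export
motif_models <- function() {
  negfb <- parse_model("
model negative_feedback
const S = 1
species X = 0
species Y = 0
param k1 = 4
param k2 = 0.8
param k3 = 0.4
param k4 = 0.25
param ki = 0.2
production_X: -> X ; k1*S/(1 + Y/ki)
decay_X: X -> ; k2*X
production_Y: -> Y ; k3*X
decay_Y: Y -> ; k4*Y
end")
  posfb <- parse_model("
model positive_feedback
const S = 1
species X = 0
species Y = 0
param k1 = 4
param k2 = 0.8
param k3 = 0.4
param k4 = 0.25
param ki = 0.2
production_X: -> X ; k1*S*(0.1 + Y)/(ki + Y)
decay_X: X -> ; k2*X
production_Y: -> Y ; k3*X
decay_Y: Y -> ; k4*Y
end")
  ffwd <- parse_model("
model feed_forward
const S = 1
species X = 0
species Y = 0
param k1 = 4
param k2 = 0.8
param k3 = 0.4
param k4 = 0.25
production_X: -> X ; k1*S
decay_X: X -> ; k2*X
production_Y: -> Y ; k3*S*X
decay_Y: Y -> ; k4*Y
end")
  list(negative_feedback = negfb, positive_feedback = posfb,
       feed_forward = ffwd)
}

#' Observation map shared by the motif fixtures
#'
#' Both states are observed, in arbitrary units, through the standard linear
#' observation function with scale factor 100.
#'
#' @param scale_factor the common scale factor.
#' @return an [observation_map()] with observables `X_obs`, `Y_obs`.
#' @export
motif_observation_map <- function(scale_factor = 100) {
  observation_map(c("X_obs", "Y_obs"), c("X", "Y"), scale_factor)
}

#' Reduced Smad7/Ski negative-feedback model variants
#'
#' Toy analogues of three alternative hypotheses for Smad7-mediated negative
#' feedback in TGF-beta signalling. A driver species `D` (the active
#' signalling complex, initially present) induces transcription of `Smad7`
#' and `Ski`; Ski represses Smad7 transcription through a saturable
#' inhibition term `kV*D/(km + D) * I50/(I50 + Ski)` carrying the Michaelis
#' constant `km` and inhibition constant `I50`; Smad7 degrades the driver,
#' closing the feedback loop. The variants differ in mechanism:
#' \describe{
#'   \item{model_1}{Smad7 acts catalytically on driver degradation (it
#'     participates but is not consumed).}
#'   \item{model_2}{Smad7 is consumed by the driver-degradation reaction
#'     (same rate law, different stoichiometry).}
#'   \item{model_3}{as model_2, but Ski decays by second-order mass action
#'     (`kdegs*Ski^2`).}
#' }
#'
#' @return a named list of three [kinetic_model] objects.
#' @export
smad_demo_models <- function() {
  base <- "
model %s
species D = 1
species Smad7 = 0.05
species Ski = 0.05
param kV = 2
param km = 0.5
param I50 = 0.3
param kski = 0.5
param kdeg7 = 0.8
param kdegs = 0.3
param kfb = 1.5
Smad7Transcription: -> Smad7 ; kV*D/(km + D) * I50/(I50 + Ski)
SkiTranscription: -> Ski ; kski*D
Smad7Deg: Smad7 -> ; kdeg7*Smad7
%s
%s
end"
  m1 <- parse_model(sprintf(base, "smad_model_1",
    "SkiDeg: Ski -> ; kdegs*Ski",
    "Feedback: D -> ; kfb*Smad7*D"))
  m2 <- parse_model(sprintf(base, "smad_model_2",
    "SkiDeg: Ski -> ; kdegs*Ski",
    "Feedback: D + Smad7 -> ; kfb*Smad7*D"))
  m3 <- parse_model(sprintf(base, "smad_model_3",
    "SkiDeg: Ski -> ; kdegs*Ski^2",
    "Feedback: D + Smad7 -> ; kfb*Smad7*D"))
  list(model_1 = m1, model_2 = m2, model_3 = m3)
}

#' Generate synthetic replicated time-course data from a model
#'
#' Emulates the study design used for calibration: observables sampled at
#' 0, 1, 2, 4, 8, 12 h with 6 biological replicates, mapped from model units
#' to arbitrary units through the observation function, with optional
#' measurement noise. Protein observables can be derived from mRNA
#' observables by the lag rule `protein(t) = magnitude * mRNA(t - lag)`
#' (values before the lag hold the baseline level), mirroring the assumption
#' that protein appears 30 minutes after the mRNA at 100 times the magnitude.
#'
#' @param model a [kinetic_model] (the generating truth).
#' @param times sampling times in hours.
#' @param replicates biological replicates per time point.
#' @param noise `"gaussian_cv"` (Gaussian with sd = cv * signal, clipped at
#'   0), `"lognormal"` (log-normal with log-sd `cv`) or `"none"`.
#' @param cv noise coefficient of variation.
#' @param map an [observation_map()]; defaults to observing every dynamic
#'   species with scale factor 100.
#' @param true_values optional named overrides of the generating parameters.
#' @param protein_rule optional list describing derived protein observables:
#'   `from` (named character: protein observable -> source mRNA observable),
#'   `lag` (hours, default 0.5), `magnitude` (default 100) and `noisy`
#'   (logical, default TRUE: replicate noise is applied to derived profiles
#'   too).
#' @param seed integer seed; identical seeds give identical tables.
#' @return an [experiment_table()].
#' @export
generate_data <- function(model, times = c(0, 1, 2, 4, 8, 12), replicates = 6,
                          noise = c("gaussian_cv", "none", "lognormal"),
                          cv = 0.1, map = NULL, true_values = NULL,
                          protein_rule = NULL, seed = 1) {
  noise <- match.arg(noise)
  if (is.null(map)) {
    sp <- model$species$name[!model$species$fixed]
    map <- observation_map(paste0(sp, "_obs"), sp, 100)
  }
  lag <- if (is.null(protein_rule)) 0 else protein_rule$lag %||% 0.5
  magnitude <- if (is.null(protein_rule)) 100 else protein_rule$magnitude %||% 100
  sim_times <- sort(unique(c(times, pmax(times - lag, 0))))
  tc <- simulate(model, times = sim_times, parameter_overrides = true_values)
  truth_all <- map_observation(tc, map)
  truth <- truth_all[match(times, sim_times), , drop = FALSE]

  obs_names <- map$observable
  if (!is.null(protein_rule)) {
    for (p in names(protein_rule$from)) {
      src <- protein_rule$from[[p]]
      lagged <- truth_all[match(pmax(times - lag, 0), sim_times), src]
      truth <- cbind(truth, magnitude * lagged)
      colnames(truth)[ncol(truth)] <- p
    }
    obs_names <- colnames(truth)
  }

  with_seed(seed, {
    vals <- array(NA_real_, dim = c(length(times), replicates, length(obs_names)),
                  dimnames = list(NULL, NULL, obs_names))
    noisy_cols <- if (is.null(protein_rule) || isTRUE(protein_rule$noisy %||% TRUE))
      obs_names else setdiff(obs_names, names(protein_rule$from))
    n_clipped <- 0L
    for (k in seq_along(obs_names)) {
      mu <- truth[, obs_names[[k]]]
      for (r in seq_len(replicates)) {
        v <- if (noise == "none" || !obs_names[[k]] %in% noisy_cols) {
          mu
        } else if (noise == "gaussian_cv") {
          mu + stats::rnorm(length(mu), 0, cv * abs(mu))
        } else {
          mu * stats::rlnorm(length(mu), 0, cv)
        }
        n_clipped <- n_clipped + sum(v < 0)
        vals[, r, k] <- pmax(v, 0)
      }
    }
    if (n_clipped > 0)
      warning(n_clipped, " negative value(s) clipped at 0 after noise")
    experiment_table(times, vals,
                     provenance = sprintf("synthetic from model '%s' (noise=%s, cv=%g, seed=%d)",
                                          model$name, noise, cv, seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesize a raw qPCR plate from an expression table (inverse 2^-ddCt)
#'
#' Builds cycle-threshold values that [ddct_normalize()] maps back onto the
#' expression table: each target gene gets
#' `Ct = mean(reference Ct) - log2(expression)` plus optional Gaussian Ct
#' noise, and the reference genes get fixed Ct values. Because ddCt
#' normalization is relative to the baseline calibrator, the recovery is
#' exact (at zero Ct noise) when each observable's baseline (t = t0)
#' replicates have geometric mean 1; use `rescale = TRUE` to divide each
#' observable by that baseline geometric mean first (the fold-change-from-
#' baseline convention).
#'
#' @param table an [experiment_table()] with strictly positive values.
#' @param reference_ct named numeric of reference-gene Ct values (constant
#'   across samples).
#' @param ct_noise_sd Gaussian noise on synthesized Ct values (cycles).
#' @param rescale divide observables by their baseline geometric mean first.
#' @param seed integer seed.
#' @return a [qpcr_plate()].
#' @export
synthesize_qpcr <- function(table,
                            reference_ct = c(B2M = 20, PPIA = 22, GAPDH = 18,
                                             ACTB = 19),
                            ct_noise_sd = 0, rescale = TRUE, seed = 1) {
  stopifnot(inherits(table, "experiment_table"))
  v <- table$values
  if (any(v <= 0, na.rm = TRUE))
    stop("expression values must be strictly positive to synthesize Ct",
         call. = FALSE)
  if (rescale) {
    for (k in seq_along(table$observables)) {
      g0 <- exp(mean(log(v[1, , k]), na.rm = TRUE))
      v[, , k] <- v[, , k] / g0
    }
  }
  nt <- length(table$times); nr <- table$n_replicates
  genes <- c(names(reference_ct), table$observables)
  ct <- matrix(NA_real_, nt * nr, length(genes),
               dimnames = list(NULL, genes))
  time <- rep(table$times, each = nr)
  replicate <- rep(seq_len(nr), times = nt)
  ref_mean <- mean(reference_ct)
  with_seed(seed, {
    for (i in seq_len(nt * nr)) {
      ti <- (i - 1L) %/% nr + 1L
      ri <- (i - 1L) %% nr + 1L
      ct[i, names(reference_ct)] <- reference_ct
      ct[i, table$observables] <- ref_mean - log2(v[ti, ri, ])
      if (ct_noise_sd > 0)
        ct[i, ] <- ct[i, ] + stats::rnorm(length(genes), 0, ct_noise_sd)
    }
  })
  qpcr_plate(ct, time, replicate, reference_genes = names(reference_ct))
}
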