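new_estimation_archive <- function(problem, sets, ranked = FALSE) {
  structure(list(problem = problem, sets = sets, ranked = ranked),
            class = "estimation_archive")
}

archive_param_names <- function(archive) archive$problem$free$name

#' Multi-start calibration of a kinetic model (repeat parameter estimations)
#'
#' The central fitting function. Runs `n_runs` independent parameter
#' estimations, each seeded with `seed + i` and started from random
#' (log-uniform) values, and collects the results into a ranked
#' `estimation_archive`. Each run uses the configured global optimizer
#' (genetic algorithm by default). Runs are scheduled over at most
#' `max_workers` worker processes; because every run owns its RNG stream,
#' results are identical for any worker count.
#'
#' @param problem a [fit_problem()].
#' @param n_runs number of independent estimations.
#' @param config an [optimizer_config()].
#' @param seed integer base seed; run `i` uses `seed + i`.
#' @param max_workers maximum concurrent runs (forked workers where the
#'   platform supports them).
#' @return an `estimation_archive`; see [rank_archive()], [chaser()],
#'   [coef.estimation_archive()] and [plot.estimation_archive()].
#' @examples
#' \donttest{
#' mods <- motif_models()
#' dat <- generate_data(mods$negative_feedback, noise = "none")
#' prob <- fit_problem(mods$negative_feedback, dat, motif_observation_map(),
#'                     free = c("k1", "k2", "k3"))
#' fit <- calibrate(prob, n_runs = 3,
#'                  config = optimizer_config(population_size = 20,
#'                                            generations = 30),
#'                  seed = 1)
#' coef(fit)
#' }
#' @export
calibrate <- function(problem, n_runs = 10, config = optimizer_config(),
                      seed = 1, max_workers = 1) {
  stopifnot(inherits(problem, "fit_problem"), n_runs >= 1, max_workers >= 1)
  objective <- make_objective(problem)
  lower <- stats::setNames(problem$free$lower, problem$free$name)
  upper <- stats::setNames(problem$free$upper, problem$free$name)

  run_one <- function(i) {
    cfg <- config
    cfg$seed <- seed + i
    tryCatch({
      ps <- if (config$algorithm == "genetic") {
        genetic_algorithm(objective, lower, upper, cfg)
      } else {
        start <- sample_start(problem, seed = cfg$seed)
        hooke_jeeves(objective, lower, upper, start, cfg)
      }
      ps$run_id <- i
      ps$seed <- cfg$seed
      ps
    }, error = function(e) structure(conditionMessage(e), class = "run_failure"))
  }

  ids <- seq_len(n_runs)
  results <- if (max_workers > 1 &&
                 .Platform$OS.type == "unix" &&
                 requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(ids, run_one, mc.cores = max_workers)
  } else {
    lapply(ids, run_one)
  }
  failed <- vapply(results, inherits, TRUE, "run_failure")
  if (all(failed))
    stop("all estimation runs failed; first error: ", results[[1]], call. = FALSE)
  if (any(failed))
    warning(sum(failed), " of ", n_runs, " estimation runs failed and were dropped")
  results <- results[!failed]

  sets <- do.call(rbind, lapply(results, function(ps) {
    data.frame(run_id = ps$run_id, seed = ps$seed, algorithm = ps$algorithm,
               chased = ps$chased, source_id = NA_integer_, rss = ps$rss,
               as.list(ps$values), check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  rank_archive(new_estimation_archive(problem, sets))
}

#' @rdname calibrate
#' @export
repeat_estimation <- calibrate

#' Rank an estimation archive by objective value
#'
#' Sorts parameter sets by RSS ascending, ties broken by run id, and marks the
#' archive as ranked.
#'
#' @param archive an `estimation_archive`.
#' @return the ranked archive.
#' @export
rank_archive <- function(archive) {
  stopifnot(inherits(archive, "estimation_archive"))
  o <- order(archive$sets$rss, archive$sets$run_id)
  archive$sets <- archive$sets[o, , drop = FALSE]
  rownames(archive$sets) <- NULL
  archive$ranked <- TRUE
  archive
}

#' Subset an estimation archive before analysis or plotting
#'
#' Sub-optimal parameter sets can distort distributions and relationships;
#' truncation keeps the best-ranking subset. `"fraction"` keeps the top
#' fraction (e.g. 0.10 for the top 10%), `"count"` the top `value` sets, and
#' `"rss_cutoff"` all sets with RSS at or below `value`.
#'
#' @param archive an `estimation_archive` (ranked first if necessary).
#' @param mode one of `"fraction"`, `"count"`, `"rss_cutoff"`.
#' @param value the fraction, count or cutoff.
#' @return the truncated (ranked) archive.
#' @export
truncate_archive <- function(archive, mode = c("fraction", "count", "rss_cutoff"),
                             value) {
  mode <- match.arg(mode)
  archive <- rank_archive(archive)
  n <- nrow(archive$sets)
  keep <- switch(mode,
    fraction = {
      if (value <= 0 || value > 1)
        stop("fraction must be in (0, 1]", call. = FALSE)
      seq_len(max(1L, floor(n * value)))
    },
    count = seq_len(min(n, max(1L, as.integer(value)))),
    rss_cutoff = which(archive$sets$rss <= value))
  archive$sets <- archive$sets[keep, , drop = FALSE]
  archive
}

#' Chaser estimations: local refinement of global candidates
#'
#' Takes the best parameter sets found by the global search, inserts each into
#' the model and drives it to a nearby minimum with Hooke-Jeeves pattern
#' search. Refined sets are appended to the archive with a `chased` flag; each
#' refined RSS is no worse than its source.
#'
#' @param archive a ranked `estimation_archive`.
#' @param top_k number of best sets to refine (clipped to the archive size
#'   with a warning), or
#' @param top_fraction alternatively, the best fraction to refine.
#' @param config an [optimizer_config()]; the demo protocol uses
#'   `tolerance = 1e-10`, `iteration_limit = 1000`.
#' @return the re-ranked archive including the chased sets.
#' @export
chaser <- function(archive, top_k = 3, top_fraction = NULL,
                   config = optimizer_config(algorithm = "hooke_jeeves",
                                             tolerance = 1e-10,
                                             iteration_limit = 1000)) {
  stopifnot(inherits(archive, "estimation_archive"))
  if (!archive$ranked) archive <- rank_archive(archive)
  n <- nrow(archive$sets)
  k <- if (!is.null(top_fraction)) max(1L, floor(n * top_fraction)) else top_k
  if (k > n) {
    warning("selection larger than archive; clipped to ", n, " sets")
    k <- n
  }
  if (k < 1) stop("chaser selection is empty", call. = FALSE)

  problem <- archive$problem
  objective <- make_objective(problem)
  lower <- stats::setNames(problem$free$lower, problem$free$name)
  upper <- stats::setNames(problem$free$upper, problem$free$name)
  pn <- archive_param_names(archive)
  next_id <- max(archive$sets$run_id) + 1L

  chased_rows <- lapply(seq_len(k), function(i) {
    src <- archive$sets[i, ]
    start <- stats::setNames(as.numeric(src[1, pn]), pn)
    ps <- hooke_jeeves(objective, lower, upper, start, config)
    rss <- min(ps$rss, src$rss)   # pattern search never worsens, belt-and-braces
    data.frame(run_id = next_id + i - 1L, seed = src$seed,
               algorithm = "hooke_jeeves", chased = TRUE,
               source_id = src$run_id, rss = rss,
               as.list(ps$values), check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  archive$sets <- rbind(archive$sets, do.call(rbind, chased_rows))
  rank_archive(archive)
}

#' @export
print.estimation_archive <- function(x, ...) {
  cat(sprintf("Estimation archive: %d parameter sets (%d chased), model '%s'%s\n",
              nrow(x$sets), sum(x$sets$chased), x$problem$model$name,
              if (x$ranked) ", ranked" else ""))
  cat(sprintf("RSS: best %.6g, median %.6g, worst %.6g\n",
              min(x$sets$rss), stats::median(x$sets$rss), max(x$sets$rss)))
  invisible(x)
}

#' @export
summary.estimation_archive <- function(object, top_fraction = 1, ...) {
  a <- if (top_fraction < 1)
    truncate_archive(object, "fraction", top_fraction) else rank_archive(object)
  pn <- archive_param_names(a)
  qs <- t(vapply(pn, function(p)
    stats::quantile(a$sets[[p]], c(0.25, 0.5, 0.75)), numeric(3)))
  out <- list(n_sets = nrow(a$sets), n_chased = sum(a$sets$chased),
              rss = summary(a$sets$rss), parameter_quartiles = qs,
              best = coef(a))
  class(out) <- "summary.estimation_archive"
  out
}

#' @export
print.summary.estimation_archive <- function(x, ...) {
  cat(sprintf("Archive of %d parameter sets (%d chased)\n", x$n_sets, x$n_chased))
  cat("RSS distribution:\n"); print(x$rss)
  cat("Best parameter set:\n"); print(x$best)
  cat("Parameter quartiles:\n"); print(x$parameter_quartiles)
  invisible(x)
}

#' Best parameter values from an archive
#'
#' @param object an `estimation_archive`.
#' @param ... unused.
#' @return named numeric of the best-ranking (lowest RSS) parameter set.
#' @export
coef.estimation_archive <- function(object, ...) {
  a <- rank_archive(object)
  pn <- archive_param_names(a)
  stats::setNames(as.numeric(a$sets[1, pn]), pn)
}

#' Extract the i-th ranked parameter set
#'
#' @param archive an `estimation_archive`.
#' @param i rank (1 = best).
#' @return a `parameter_set`.
#' @export
get_parameter_set <- function(archive, i = 1) {
  a <- rank_archive(archive)
  pn <- archive_param_names(a)
  row <- a$sets[i, ]
  new_parameter_set(stats::setNames(as.numeric(row[1, pn]), pn), row$rss,
                    run_id = row$run_id, seed = row$seed,
                    algorithm = row$algorithm, chased = row$chased)
}

#' Simulate the fitted model at the best (or a chosen) parameter set
#'
#' @param object an `estimation_archive`.
#' @param times output times (defaults to a fine grid over the data range).
#' @param rank which ranked set to use.
#' @param units `"data"` returns mapped observables in data units;
#'   `"model"` returns the raw species time course.
#' @param ... unused.
#' @return a data.frame (time plus observables) or `time_course`.
#' @export
predict.estimation_archive <- function(object, times = NULL, rank = 1,
                                       units = c("data", "model"), ...) {
  units <- match.arg(units)
  problem <- object$problem
  if (is.null(times)) {
    tr <- range(problem$data$times)
    times <- seq(tr[1], tr[2], length.out = 101)
  }
  ps <- get_parameter_set(object, rank)
  tc <- simulate(problem$model, times = times, parameter_overrides = ps$values,
                 compiled = problem$compiled)
  if (units == "model") return(tc)
  data.frame(time = times, map_observation(tc, problem$map), check.names = FALSE)
}

#' Weighted residuals of the best-ranking parameter set
#'
#' @param object an `estimation_archive`.
#' @param rank which ranked set to use.
#' @param ... unused.
#' @return array time x replicate x observable of weighted residuals.
#' @export
residuals.estimation_archive <- function(object, rank = 1, ...) {
  problem <- object$problem
  ps <- get_parameter_set(object, rank)
  tc <- simulate(problem$model, times = problem$data$times,
                 parameter_overrides = ps$values, compiled = problem$compiled)
  sim_obs <- map_observation(tc, problem$map)
  res <- problem$data$values
  for (k in seq_along(problem$data$observables))
    res[, , k] <- (res[, , k] - sim_obs[, k]) / problem$sigma[, k]
  res
}

#' @export
as.data.frame.estimation_archive <- function(x, ...) x$sets

#' Persist and restore estimation archives as CSV
#'
#' Columns: `run_id`, `seed`, `algorithm`, `chased`, `source_id`, `rss`, then
#' one column per free parameter.
#'
#' @param archive an `estimation_archive`.
#' @param path CSV file.
#' @export
write_archive <- function(archive, path) {
  utils::write.csv(archive$sets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_archive
#' @param problem the `fit_problem` the archive belongs to.
#' @export
read_archive <- function(path, problem) {
  sets <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rank_archive(new_estimation_archive(problem, sets))
}
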