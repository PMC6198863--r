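#' Information criteria from a residual sum of squares
#'
#' Gaussian-likelihood forms on an RSS objective:
#' `AIC = n*log(rss/n) + 2k`, the small-sample corrected
#' `AICc = AIC + 2k(k+1)/(n-k-1)`, and `BIC = n*log(rss/n) + k*log(n)`,
#' where `n` counts non-missing replicate data points and `k` the free
#' (estimated) parameters. Lower values indicate better agreement with the
#' data after penalizing model complexity. When the criteria are computed
#' from an sd-weighted RSS they treat the replicate standard deviations as
#' the true error scales.
#'
#' @param rss objective value (> 0; an exact zero returns `-Inf` with a
#'   warning).
#' @param n number of data points.
#' @param k number of free parameters; AICc requires `n > k + 1`.
#' @return the criterion value (scalar, vectorized over `rss`).
#' @examples
#' aicc(10, 36, 5)   # -34.114
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1)
    stop("AICc undefined: requires n > k + 1", call. = FALSE)
  out <- aic(rss, n, k) + 2 * k * (k + 1) / (n - k - 1)
  out
}

#' @rdname aicc
#' @export
aic <- function(rss, n, k) {
  if (any(rss < 0)) stop("rss must be non-negative", call. = FALSE)
  if (any(rss == 0)) {
    warning("rss of 0: criterion is -Inf")
    return(ifelse(rss == 0, -Inf, n * log(rss / n) + 2 * k))
  }
  n * log(rss / n) + 2 * k
}

#' @rdname aicc
#' @export
bic <- function(rss, n, k) {
  if (any(rss < 0)) stop("rss must be non-negative", call. = FALSE)
  if (any(rss == 0)) {
    warning("rss of 0: criterion is -Inf")
    return(ifelse(rss == 0, -Inf, n * log(rss / n) + k * log(n)))
  }
  n * log(rss / n) + k * log(n)
}

#' Calibrate several competing models against the same data
#'
#' The model-selection workhorse: runs [calibrate()] for each candidate
#' fit problem, all sharing the same experiment table, with the base seed
#' offset by model index so that runs are reproducible yet independent
#' across models. Archives are returned in input order; rank them with
#' [select_models()].
#'
#' @param problems a list of [fit_problem()]s sharing one data set (the
#'   observation maps may target different species per model).
#' @param n_runs estimations per model.
#' @param config an [optimizer_config()].
#' @param seed base seed; model `m` uses `seed + (m-1)*n_runs`.
#' @param chase_top if > 0, additionally refine this many best sets per model
#'   with [chaser()] (local config `chase_config`).
#' @param chase_config [optimizer_config()] for the chaser.
#' @param max_workers passed to [calibrate()].
#' @return a named list of `estimation_archive`s.
#' @export
multi_model_fit <- function(problems, n_runs = 10, config = optimizer_config(),
                            seed = 1, chase_top = 0,
                            chase_config = optimizer_config(
                              algorithm = "hooke_jeeves",
                              tolerance = 1e-10, iteration_limit = 1000),
                            max_workers = 1) {
  stopifnot(length(problems) >= 1,
            all(vapply(problems, inherits, TRUE, "fit_problem")))
  ref <- problems[[1]]$data
  for (p in problems[-1])
    if (!isTRUE(all.equal(p$data$times, ref$times)) ||
        !isTRUE(all.equal(p$data$values, ref$values)))
      stop("all problems must share the same experiment table", call. = FALSE)
  archives <- lapply(seq_along(problems), function(m) {
    a <- calibrate(problems[[m]], n_runs = n_runs, config = config,
                   seed = seed + (m - 1L) * n_runs, max_workers = max_workers)
    if (chase_top > 0) a <- chaser(a, top_k = chase_top, config = chase_config)
    a
  })
  names(archives) <- vapply(problems, function(p) p$model$name, "")
  archives
}

#' Rank competing models by information criteria
#'
#' Computes AICc and BIC for every parameter set of every archive and ranks
#' the models by their best (lowest) criterion value. Models whose data-point
#' count does not support the AICc correction (`n <= k + 1`) are flagged and
#' excluded from the AICc ranking.
#'
#' @param archives a (named) list of `estimation_archive`s, e.g. from
#'   [multi_model_fit()].
#' @param criterion primary ranking criterion, `"aicc"` or `"bic"`.
#' @return an object of class `selection_report`: `models` (data.frame with
#'   `model`, `n`, `k`, `best_rss`, `best_aicc`, `best_bic`, `delta`,
#'   `rank`), `per_set` (list of per-set criterion data.frames, for violin
#'   plots), `criterion` and `flagged` (models excluded from AICc ranking).
#' @export
select_models <- function(archives, criterion = c("aicc", "bic")) {
  criterion <- match.arg(criterion)
  stopifnot(length(archives) >= 1,
            all(vapply(archives, inherits, TRUE, "estimation_archive")))
  if (is.null(names(archives)))
    names(archives) <- vapply(archives, function(a) a$problem$model$name, "")

  per_set <- list(); rows <- list(); flagged <- character()
  for (nm in names(archives)) {
    a <- rank_archive(archives[[nm]])
    n <- a$problem$n_points
    k <- nrow(a$problem$free)
    rss <- a$sets$rss
    aicc_ok <- n > k + 1
    if (!aicc_ok) flagged <- c(flagged, nm)
    df <- data.frame(model = nm, run_id = a$sets$run_id, chased = a$sets$chased,
                     rss = rss,
                     aicc = if (aicc_ok) aicc(rss, n, k) else NA_real_,
                     bic = bic(rss, n, k), stringsAsFactors = FALSE)
    per_set[[nm]] <- df
    rows[[nm]] <- data.frame(
      model = nm, n = n, k = k, best_rss = min(rss),
      best_aicc = if (aicc_ok) min(df$aicc) else NA_real_,
      best_bic = min(df$bic), stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, rows)
  score <- if (criterion == "aicc") models$best_aicc else models$best_bic
  models$delta <- score - min(score, na.rm = TRUE)
  models$rank <- rank(score, ties.method = "first", na.last = "keep")
  models <- models[order(models$rank), , drop = FALSE]
  rownames(models) <- NULL
  structure(list(models = models, per_set = per_set, criterion = criterion,
                 flagged = flagged),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Model selection by %s (lower is better):\n", toupper(x$criterion)))
  print(x$models, row.names = FALSE, digits = 6)
  if (length(x$flagged))
    cat("Excluded from AICc ranking (n <= k + 1):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Persist a selection report
#'
#' Writes the model summary as JSON and the per-set criteria as CSV.
#'
#' @param report a [select_models()] result.
#' @param json_path,csv_path output files (either may be `NULL`).
#' @export
write_selection <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(criterion = report$criterion,
                              flagged = report$flagged,
                              models = report$models),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(do.call(rbind, c(report$per_set, make.row.names = FALSE)),
                     csv_path, row.names = FALSE, quote = FALSE)
  invisible(report)
}
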