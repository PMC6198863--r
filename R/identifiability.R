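#' Profile likelihood of one parameter
#'
#' A profile likelihood is a parameter scan of re-optimizations starting from
#' a best parameter set: the profiled parameter is fixed at each point of a
#' log10-spaced grid spanning `span_orders` decades either side of its best
#' value (intersected with the problem bounds) and all remaining free
#' parameters are re-optimized by Hooke-Jeeves. The scan sweeps outward from
#' the best value in both directions, warm-starting each re-optimization from
#' the neighbouring point's solution, which keeps profiles smooth and cheap.
#' The profile is only meaningful when `best` is (near-)optimal; that is the
#' caller's responsibility (chase candidates first, see [chaser()]).
#'
#' @param problem a [fit_problem()].
#' @param best a `parameter_set` (see [get_parameter_set()]) or named numeric
#'   of all free-parameter values.
#' @param parameter name of the parameter to profile.
#' @param span_orders decades scanned either side of the best value.
#' @param n_points grid points per direction.
#' @param local_config [optimizer_config()] for the re-optimizations; the
#'   demo protocol uses `tolerance = 1e-6`, `iteration_limit = 50`.
#' @return an object of class `profile_curve`: the profiled `parameter`, its
#'   `best_value` and `best_rss`, and `points` (data.frame: `value`, `rss`,
#'   one column per co-parameter), sorted by fixed value.
#' @export
profile_likelihood <- function(problem, best, parameter,
                               span_orders = 3, n_points = 20,
                               local_config = optimizer_config(
                                 algorithm = "hooke_jeeves",
                                 tolerance = 1e-6, iteration_limit = 50)) {
  stopifnot(inherits(problem, "fit_problem"))
  values <- if (inherits(best, "parameter_set")) best$values else best
  if (!parameter %in% problem$free$name)
    stop("'", parameter, "' is not a free parameter of the problem", call. = FALSE)
  if (!all(problem$free$name %in% names(values)))
    stop("'best' must supply every free parameter", call. = FALSE)
  best_rss <- if (inherits(best, "parameter_set") && is.finite(best$rss))
    best$rss else weighted_rss(problem, values)
  if (!is.finite(best_rss))
    stop("best parameter set has non-finite RSS; profile from an optimum",
         call. = FALSE)

  i <- match(parameter, problem$free$name)
  lb <- problem$free$lower[[i]]; ub <- problem$free$upper[[i]]
  v0 <- values[[parameter]]
  others <- setdiff(problem$free$name, parameter)
  lo <- stats::setNames(problem$free$lower, problem$free$name)[others]
  hi <- stats::setNames(problem$free$upper, problem$free$name)[others]

  grid_side <- function(dir) {
    g <- v0 * 10^(dir * seq_len(n_points) / n_points * span_orders)
    g[g >= lb & g <= ub]
  }

  scan_side <- function(grid) {
    start <- values[others]
    out <- vector("list", length(grid))
    for (j in seq_along(grid)) {
      obj <- make_objective(problem, fixed = stats::setNames(grid[[j]], parameter))
      if (length(others)) {
        ps <- hooke_jeeves(obj, lo, hi, start, local_config)
        rss <- ps$rss
        if (is.finite(rss)) start <- ps$values
        co <- ps$values
      } else {
        rss <- obj(numeric(0))
        co <- stats::setNames(numeric(0), character(0))
      }
      out[[j]] <- c(value = grid[[j]], rss = rss, co)
    }
    out
  }

  up <- scan_side(grid_side(+1))
  down <- scan_side(grid_side(-1))
  centre <- list(c(value = v0, rss = best_rss, values[others]))
  pts <- as.data.frame(do.call(rbind, c(rev(down), centre, up)))
  rownames(pts) <- NULL

  structure(list(parameter = parameter, best_value = v0, best_rss = best_rss,
                 points = pts, span_orders = span_orders, n_points = n_points,
                 local_config = local_config,
                 source_id = if (inherits(best, "parameter_set"))
                   best$run_id else NA_integer_),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf(
    "Profile likelihood of '%s': best %.4g (RSS %.6g), %d scan points in [%.3g, %.3g]\n",
    x$parameter, x$best_value, x$best_rss, nrow(x$points),
    min(x$points$value), max(x$points$value)))
  invisible(x)
}

#' Likelihood-ratio confidence threshold for profile likelihoods
#'
#' For an sd-weighted RSS the pointwise likelihood-ratio threshold at level
#' `alpha` is `best_rss + qchisq(alpha, df = 1)` (`chi2_pointwise`). The
#' F-based form, `best_rss * (1 + qf(alpha, 1, n - p)/(n - p))`, accounts for
#' an estimated error scale and converges to the chi-squared form as `n` grows.
#'
#' @param best_rss RSS at the optimum.
#' @param alpha confidence level.
#' @param mode `"chi2_pointwise"` or `"f_based"`.
#' @param n_points_total,n_free data-point and free-parameter counts
#'   (`f_based` mode only; requires `n > p`).
#' @return an object of class `threshold_spec` with the numeric `value`.
#' @export
confidence_threshold <- function(best_rss, alpha = 0.95,
                                 mode = c("chi2_pointwise", "f_based"),
                                 n_points_total = NULL, n_free = NULL) {
  mode <- match.arg(mode)
  stopifnot(best_rss >= 0, alpha > 0, alpha < 1)
  value <- if (mode == "chi2_pointwise") {
    best_rss + stats::qchisq(alpha, df = 1)
  } else {
    if (is.null(n_points_total) || is.null(n_free))
      stop("f_based mode needs n_points_total and n_free", call. = FALSE)
    n <- n_points_total; p <- n_free
    if (n <= p) stop("f_based threshold requires n > p", call. = FALSE)
    best_rss * (1 + stats::qf(alpha, 1, n - p) / (n - p))
  }
  structure(list(alpha = alpha, mode = mode, best_rss = best_rss,
                 value = value),
            class = "threshold_spec")
}

threshold_value <- function(threshold) {
  if (inherits(threshold, "threshold_spec")) threshold$value else threshold
}

#' Classify a profile likelihood curve
#'
#' A completely flat profile (RSS range below `flatness_tol` relative to the
#' best RSS) marks the parameter structurally non-identifiable: it is
#' algebraically compensated by others, so the confidence interval is
#' unbounded on both sides. Because the scan only samples parameter space,
#' structural calls are flagged as *suspected* and should be investigated
#' (e.g. with [coparameter_trace()]). Otherwise the threshold crossings are
#' located on a cubic-spline interpolation of RSS against log10(value); a
#' crossing on both sides gives an identifiable parameter with the crossings
#' as confidence bounds, a crossing on one side (or none) a practically
#' non-identifiable one with the uncrossed bound(s) infinite.
#'
#' @param curve a [profile_likelihood()] result (at least 5 scan points).
#' @param threshold a [confidence_threshold()] or a numeric RSS threshold;
#'   must exceed the curve's best RSS.
#' @param flatness_tol relative flatness tolerance.
#' @return a list: `classification` (one of `"identifiable"`,
#'   `"practically_non_identifiable"`, `"structurally_non_identifiable"`),
#'   `ci_lower`, `ci_upper` (parameter scale, may be +/-Inf) and
#'   `suspected` (TRUE for structural calls).
#' @export
classify_profile <- function(curve, threshold, flatness_tol = 1e-3) {
  stopifnot(inherits(curve, "profile_curve"))
  thr <- threshold_value(threshold)
  if (thr <= curve$best_rss)
    stop("threshold must exceed the best RSS", call. = FALSE)
  pts <- curve$points[is.finite(curve$points$rss), , drop = FALSE]
  if (nrow(pts) < 5)
    stop("need at least 5 finite scan points to classify", call. = FALSE)

  rng <- max(pts$rss) - min(pts$rss)
  if (rng < flatness_tol * max(1, curve$best_rss))
    return(list(classification = "structurally_non_identifiable",
                ci_lower = -Inf, ci_upper = Inf, suspected = TRUE))

  lx <- log10(pts$value)
  sp <- stats::splinefun(lx, pts$rss, method = "fmm")
  x0 <- log10(curve$best_value)
  find_crossing <- function(dir) {
    side_end <- if (dir > 0) max(lx) else min(lx)
    if (abs(side_end - x0) < .Machine$double.eps) return(NA_real_)
    g <- seq(x0, side_end, length.out = 512)
    f <- sp(g) - thr
    s <- which(f[-1] > 0 & f[-length(f)] <= 0)
    if (!length(s)) return(NA_real_)
    j <- s[[1]]
    r <- stats::uniroot(function(x) sp(x) - thr, c(g[j], g[j + 1]),
                        tol = 1e-10)
    10^r$root
  }
  upper <- find_crossing(+1)
  lower <- find_crossing(-1)
  if (!is.na(lower) && !is.na(upper))
    list(classification = "identifiable", ci_lower = lower, ci_upper = upper,
         suspected = FALSE)
  else
    list(classification = "practically_non_identifiable",
         ci_lower = if (is.na(lower)) -Inf else lower,
         ci_upper = if (is.na(upper)) Inf else upper,
         suspected = FALSE)
}

#' Co-parameter trace along a profile likelihood
#'
#' The path traced by another free parameter during the re-optimizations of a
#' profile scan. Plotting this trajectory (rather than the objective value)
#' against the profiled parameter reveals compensatory relationships -- e.g.
#' a product coupling `k1*k2 = c` appears as a straight line of slope -1 in
#' log-log space -- and thereby informs model reduction.
#'
#' @param curve a [profile_likelihood()] result.
#' @param other_parameter a parameter that was free during profiling.
#' @return data.frame with `value` (fixed profiled parameter) and `other`
#'   (its re-optimized companion), one row per scan point.
#' @export
coparameter_trace <- function(curve, other_parameter) {
  stopifnot(inherits(curve, "profile_curve"))
  if (!other_parameter %in% names(curve$points) ||
      other_parameter %in% c("value", "rss", curve$parameter))
    stop("'", other_parameter, "' was not a free co-parameter of this profile",
         call. = FALSE)
  data.frame(value = curve$points$value,
             other = curve$points[[other_parameter]])
}

#' Identifiability analysis over all parameters and several best sets
#'
#' Computes profile likelihoods for every free parameter starting from each
#' supplied best parameter set (typically the chased top sets of an archive)
#' and classifies each curve against the likelihood-ratio threshold. Because
#' the profile likelihood is a local method, running it from multiple optima
#' guards against conclusions specific to one basin; parameters whose
#' classification differs across starting sets are flagged as discordant.
#'
#' @param problem a [fit_problem()].
#' @param best_sets a list of `parameter_set`s, or an `estimation_archive`
#'   (its `n_sets` best sets are used).
#' @param n_sets number of top sets when an archive is given.
#' @param parameters parameters to profile (default: all free).
#' @param alpha confidence level for the threshold.
#' @param mode threshold mode, see [confidence_threshold()].
#' @param flatness_tol see [classify_profile()].
#' @inheritParams profile_likelihood
#' @return an object of class `identifiability_report`: `table` (data.frame
#'   with `set_id`, `parameter`, `classification`, `ci_lower`, `ci_upper`,
#'   `best_value`, `best_rss`, `threshold`), `curves` (nested list of
#'   `profile_curve`s), and `discordant` (parameter names).
#' @export
profile_all <- function(problem, best_sets, n_sets = 3,
                        parameters = NULL, span_orders = 3, n_points = 20,
                        local_config = optimizer_config(
                          algorithm = "hooke_jeeves",
                          tolerance = 1e-6, iteration_limit = 50),
                        alpha = 0.95, mode = "chi2_pointwise",
                        flatness_tol = 1e-3) {
  if (inherits(best_sets, "estimation_archive")) {
    archive <- rank_archive(best_sets)
    best_sets <- lapply(seq_len(min(n_sets, nrow(archive$sets))),
                        function(i) get_parameter_set(archive, i))
  }
  if (is.null(parameters)) parameters <- problem$free$name
  rows <- list(); curves <- list()
  for (s in seq_along(best_sets)) {
    ps <- best_sets[[s]]
    set_id <- if (!is.na(ps$run_id)) ps$run_id else s
    curves[[s]] <- list()
    for (p in parameters) {
      cv <- profile_likelihood(problem, ps, p, span_orders = span_orders,
                               n_points = n_points, local_config = local_config)
      thr <- confidence_threshold(cv$best_rss, alpha = alpha, mode = mode,
                                  n_points_total = problem$n_points,
                                  n_free = nrow(problem$free))
      cl <- classify_profile(cv, thr, flatness_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = set_id, parameter = p, classification = cl$classification,
        ci_lower = cl$ci_lower, ci_upper = cl$ci_upper,
        best_value = cv$best_value, best_rss = cv$best_rss,
        threshold = thr$value, stringsAsFactors = FALSE)
      curves[[s]][[p]] <- cv
    }
  }
  table <- do.call(rbind, rows)
  discordant <- names(which(tapply(table$classification, table$parameter,
                                   function(x) length(unique(x)) > 1)))
  structure(list(table = table, curves = curves,
                 discordant = discordant, alpha = alpha),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  tab <- x$table[x$table$set_id == x$table$set_id[[1]], ]
  counts <- table(factor(tab$classification,
                         levels = c("identifiable",
                                    "practically_non_identifiable",
                                    "structurally_non_identifiable")))
  cat(sprintf(
    "Identifiability report (alpha = %.2f): %d identifiable, %d practical, %d structural (best set)\n",
    x$alpha, counts[[1]], counts[[2]], counts[[3]]))
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$discordant))
    cat("Discordant across starting sets:", paste(x$discordant, collapse = ", "), "\n")
  invisible(x)
}
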