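#' Ensemble time courses with bootstrap confidence bands
#'
#' Inserts each of the selected best parameter sets into the model, simulates
#' a time course and maps it into data units. Per time point and observable,
#' an estimator (the mean by default) is bootstrapped over the parameter sets
#' (`n_boot` resamples, percentile interval), propagating parameter
#' uncertainty into a prediction band. Experimental replicates are overlaid
#' by the plot method.
#'
#' @param archive an `estimation_archive`.
#' @param top_k number of best sets in the ensemble.
#' @param times simulation grid (defaults to 101 points over the data range).
#' @param n_boot bootstrap resamples.
#' @param estimator function aggregating across parameter sets.
#' @param ci_level confidence level of the percentile interval.
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `ensemble_timecourse`: `bands`, a named list
#'   (one per observable) of data.frames `time, center, lower, upper`;
#'   `trajectories`, the raw per-set simulated observables; and the data
#'   overlay. Sets whose simulation fails are dropped with a warning.
#' @export
ensemble_timecourse <- function(archive, top_k = 10, times = NULL,
                                n_boot = 1000, estimator = mean,
                                ci_level = 0.95, seed = 1) {
  stopifnot(inherits(archive, "estimation_archive"))
  a <- rank_archive(archive)
  k <- min(top_k, nrow(a$sets))
  if (k < 1) stop("ensemble selection is empty", call. = FALSE)
  problem <- a$problem
  if (is.null(times)) {
    tr <- range(problem$data$times)
    times <- seq(tr[1], tr[2], length.out = 101)
  }
  obs <- problem$data$observables
  traj <- array(NA_real_, dim = c(length(times), k, length(obs)),
                dimnames = list(NULL, NULL, obs))
  kept <- logical(k)
  for (i in seq_len(k)) {
    ps <- get_parameter_set(a, i)
    tc <- tryCatch(simulate(problem$model, times = times,
                            parameter_overrides = ps$values,
                            compiled = problem$compiled),
                   error = function(e) NULL)
    if (is.null(tc)) next
    traj[, i, ] <- map_observation(tc, problem$map)
    kept[i] <- TRUE
  }
  if (!any(kept)) stop("every ensemble simulation failed", call. = FALSE)
  if (!all(kept))
    warning(sum(!kept), " parameter set(s) dropped: simulation failed")
  traj <- traj[, kept, , drop = FALSE]
  m <- sum(kept)

  alpha <- (1 - ci_level) / 2
  bands <- with_seed(seed, {
    idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), nrow = m)
    lapply(stats::setNames(obs, obs), function(o) {
      tm <- traj[, , o, drop = FALSE][, , 1, drop = TRUE]
      tm <- matrix(tm, nrow = length(times))   # guard m == 1
      center <- apply(tm, 1, estimator)
      if (m == 1) {
        lower <- upper <- center
      } else {
        boot <- vapply(seq_len(n_boot),
                       function(b) apply(tm[, idx[, b], drop = FALSE], 1, estimator),
                       numeric(length(times)))
        lower <- apply(boot, 1, stats::quantile, probs = alpha)
        upper <- apply(boot, 1, stats::quantile, probs = 1 - alpha)
      }
      data.frame(time = times, center = center, lower = lower, upper = upper)
    })
  })
  structure(list(bands = bands, trajectories = traj, times = times,
                 data = problem$data, n_sets = m, ci_level = ci_level),
            class = "ensemble_timecourse")
}

#' @export
plot.ensemble_timecourse <- function(x, ...) {
  obs <- names(x$bands)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(obs)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (o in obs) {
    b <- x$bands[[o]]
    d <- x$data$values[, , o, drop = FALSE][, , 1, drop = TRUE]
    ylim <- range(b$lower, b$upper, d, na.rm = TRUE)
    plot(b$time, b$center, type = "n", ylim = ylim, xlab = "time (h)",
         ylab = o, main = o, ...)
    graphics::polygon(c(b$time, rev(b$time)), c(b$lower, rev(b$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(b$time, b$center, col = "steelblue", lwd = 2)
    graphics::matpoints(x$data$times, d, pch = 1, col = "firebrick")
  }
  invisible(x)
}

#' Likelihood-ranks (waterfall) diagnostic
#'
#' Sorted objective values against their rank of best fit across repeat
#' estimations. A flat line indicates a single repeatedly-found minimum; a
#' monotone step function maps out distinct local minima (each plateau one
#' minimum); a smooth curve indicates the estimations have not converged.
#'
#' @param archive an `estimation_archive`.
#' @return an object of class `likelihood_ranks`: data.frame `rank`, `rss`
#'   (non-decreasing).
#' @export
likelihood_ranks <- function(archive) {
  stopifnot(inherits(archive, "estimation_archive"))
  a <- rank_archive(archive)
  structure(list(data = data.frame(rank = seq_len(nrow(a$sets)),
                                   rss = a$sets$rss)),
            class = "likelihood_ranks")
}

#' @export
plot.likelihood_ranks <- function(x, log = "y", ...) {
  d <- x$data
  if (grepl("y", log) && any(d$rss <= 0)) log <- sub("y", "", log)
  plot(d$rank, d$rss, type = "b", pch = 19, log = log,
       xlab = "rank of best fit", ylab = "RSS", ...)
  invisible(x)
}

#' Parameter-estimate distributions (box plots and histograms)
#'
#' Summaries of parameter estimates across an archive, on the log10 scale by
#' default. Truncating to the best-ranking subset first (see
#' [truncate_archive()]) matters: sub-optimal sets distort the distributions
#' of well-fitting parameters.
#'
#' @param archive an `estimation_archive`.
#' @param truncate_mode,truncate_value optional truncation applied first.
#' @param log10_scale summarize log10-transformed estimates.
#' @param n_bins histogram bins per parameter.
#' @return an object of class `parameter_distributions`: per parameter the
#'   quartiles (`q25`, `median`, `q75`) and histogram `breaks`/`counts`.
#' @export
param_distributions <- function(archive, truncate_mode = NULL,
                                truncate_value = NULL, log10_scale = TRUE,
                                n_bins = 15) {
  stopifnot(inherits(archive, "estimation_archive"))
  a <- if (!is.null(truncate_mode))
    truncate_archive(archive, truncate_mode, truncate_value)
  else rank_archive(archive)
  if (nrow(a$sets) == 0) stop("archive empty after truncation", call. = FALSE)
  pn <- archive_param_names(a)
  vals <- lapply(stats::setNames(pn, pn), function(p) {
    v <- a$sets[[p]]
    if (log10_scale) log10(v) else v
  })
  summaries <- lapply(vals, function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    br <- if (diff(range(v)) == 0) c(v[1] - 0.5, v[1] + 0.5)
          else seq(min(v), max(v), length.out = n_bins + 1)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    list(q25 = q[[1]], median = q[[2]], q75 = q[[3]], iqr = q[[3]] - q[[1]],
         breaks = h$breaks, counts = h$counts)
  })
  structure(list(values = vals, summaries = summaries,
                 log10_scale = log10_scale, n_sets = nrow(a$sets)),
            class = "parameter_distributions")
}

#' @export
plot.parameter_distributions <- function(x, type = c("box", "hist"), ...) {
  type <- match.arg(type)
  lab <- if (x$log10_scale) "log10 estimate" else "estimate"
  if (type == "box") {
    graphics::boxplot(x$values, ylab = lab, las = 2, ...)
  } else {
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(x$values)),
                         mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    for (p in names(x$values))
      graphics::hist(x$values[[p]], breaks = x$summaries[[p]]$breaks,
                     main = p, xlab = lab, col = "grey80", ...)
  }
  invisible(x)
}

#' Pairwise correlations between parameter estimates
#'
#' Pearson correlations over log10 estimates across the (optionally
#' truncated) archive, used to locate linear or log-linear relationships
#' between parameters, e.g. the compensatory couplings behind practical
#' non-identifiabilities. Pairs whose |r| reaches `flag_threshold` are
#' listed with r-squared and p-value for scatter inspection.
#'
#' @inheritParams param_distributions
#' @param flag_threshold |r| at or above which a pair is flagged.
#' @return an object of class `parameter_correlations`: `r` and `p` matrices
#'   (zero-variance parameters masked as `NA`), `flagged` (data.frame of
#'   pairs with `r`, `r_squared`, `p_value`) and the log10 `estimates`.
#' @export
param_correlations <- function(archive, truncate_mode = NULL,
                               truncate_value = NULL, flag_threshold = 0.9) {
  stopifnot(inherits(archive, "estimation_archive"))
  a <- if (!is.null(truncate_mode))
    truncate_archive(archive, truncate_mode, truncate_value)
  else rank_archive(archive)
  if (nrow(a$sets) < 3)
    stop("need at least 3 parameter sets for correlations", call. = FALSE)
  pn <- archive_param_names(a)
  L <- vapply(pn, function(p) log10(a$sets[[p]]), numeric(nrow(a$sets)))
  sds <- apply(L, 2, stats::sd)
  r <- p <- matrix(NA_real_, length(pn), length(pn), dimnames = list(pn, pn))
  diag(r) <- 1; diag(p) <- 0
  flagged <- list()
  for (i in seq_along(pn)) for (j in seq_along(pn)) {
    if (j <= i) next
    if (sds[i] == 0 || sds[j] == 0) next   # correlation undefined, masked
    ct <- stats::cor.test(L[, i], L[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    if (abs(ct$estimate) >= flag_threshold)
      flagged[[length(flagged) + 1L]] <- data.frame(
        parameter_1 = pn[i], parameter_2 = pn[j], r = unname(ct$estimate),
        r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
        stringsAsFactors = FALSE)
  }
  structure(list(r = r, p = p,
                 flagged = if (length(flagged)) do.call(rbind, flagged)
                           else data.frame(),
                 estimates = L, flag_threshold = flag_threshold),
            class = "parameter_correlations")
}

#' @export
plot.parameter_correlations <- function(x, type = c("heatmap", "scatter"), ...) {
  type <- match.arg(type)
  if (type == "heatmap") {
    pn <- rownames(x$r)
    n <- length(pn)
    graphics::image(seq_len(n), seq_len(n), t(x$r[n:1, , drop = FALSE]),
                    zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(41, "Blue-Red 2"), ...)
    graphics::axis(1, seq_len(n), pn, las = 2)
    graphics::axis(2, seq_len(n), rev(pn), las = 2)
  } else {
    if (nrow(x$flagged) == 0) {
      graphics::plot.new(); graphics::title("no flagged pairs")
      return(invisible(x))
    }
    old <- graphics::par(mfrow = grDevices::n2mfrow(nrow(x$flagged)),
                         mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    for (i in seq_len(nrow(x$flagged))) {
      p1 <- x$flagged$parameter_1[[i]]; p2 <- x$flagged$parameter_2[[i]]
      plot(x$estimates[, p1], x$estimates[, p2],
           xlab = paste0("log10 ", p1), ylab = paste0("log10 ", p2),
           main = sprintf("r^2 = %.3f", x$flagged$r_squared[[i]]), pch = 19)
    }
  }
  invisible(x)
}

#' Plot profile likelihoods or co-parameter traces
#'
#' One panel per profiled parameter: scan points, spline-interpolated curve,
#' the best estimate (star) and the confidence threshold (dotted line).
#' Multiple starting sets are overlaid. With `coparameter` set, the panel
#' shows the trace of that parameter instead of the objective value.
#'
#' @param report an `identifiability_report` from [profile_all()], a named
#'   list of `profile_curve`s (one starting set), or a list of such lists.
#' @param coparameter optional co-parameter to trace on the y axis.
#' @return invisibly, the list of plotted data.frames per panel.
#' @export
plot_profiles <- function(report, coparameter = NULL) {
  curve_sets <- if (inherits(report, "identifiability_report")) report$curves
                else if (all(vapply(report, inherits, TRUE, "profile_curve")))
                  list(report)
                else report
  params <- unique(unlist(lapply(curve_sets, names)))
  thresholds <- if (inherits(report, "identifiability_report"))
    report$table$threshold[match(params, report$table$parameter)]
  else rep(NA_real_, length(params))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(params)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  out <- list()
  for (pi in seq_along(params)) {
    p <- params[[pi]]
    first <- TRUE
    for (s in seq_along(curve_sets)) {
      cv <- curve_sets[[s]][[p]]
      if (is.null(cv)) next
      if (!is.null(coparameter) && coparameter != p) {
        tr <- coparameter_trace(cv, coparameter)
        xv <- log10(tr$value); yv <- log10(tr$other)
        ylab <- paste0("log10 ", coparameter)
      } else {
        xv <- log10(cv$points$value); yv <- cv$points$rss
        ylab <- "RSS"
      }
      fin <- is.finite(yv)
      if (first) {
        plot(xv[fin], yv[fin], pch = 19, col = "firebrick",
             xlab = paste0("log10 ", p), ylab = ylab, main = p)
        if (is.null(coparameter) && !is.na(thresholds[[pi]]))
          graphics::abline(h = thresholds[[pi]], lty = 3, col = "darkgreen")
        first <- FALSE
      } else graphics::points(xv[fin], yv[fin], pch = 19,
                              col = grDevices::adjustcolor("firebrick", 0.5))
      if (sum(fin) >= 4) {
        sp <- stats::splinefun(xv[fin], yv[fin], method = "fmm")
        g <- seq(min(xv[fin]), max(xv[fin]), length.out = 200)
        graphics::lines(g, sp(g), col = "grey40")
      }
      if (is.null(coparameter))
        graphics::points(log10(cv$best_value), cv$best_rss, pch = 8, cex = 1.5)
      out[[p]] <- data.frame(x = xv, y = yv)
    }
  }
  invisible(out)
}

#' Plot model-selection results
#'
#' Per-model distributions of the criterion over all parameter sets
#' (box plots standing in for violins) and a bar comparison of the
#' best values.
#'
#' @param report a [select_models()] result.
#' @param criterion `"aicc"` or `"bic"`.
#' @return invisibly, the per-model criterion values plotted.
#' @export
plot_selection <- function(report, criterion = NULL) {
  stopifnot(inherits(report, "selection_report"))
  criterion <- criterion %||% report$criterion
  vals <- lapply(report$per_set, function(df) df[[criterion]])
  best <- vapply(vals, min, 0)
  old <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::boxplot(vals, ylab = toupper(criterion), las = 2,
                    main = "distribution per model")
  graphics::barplot(best, ylab = paste("best", toupper(criterion)), las = 2,
                    main = "best value per model")
  invisible(vals)
}

#' Render a diagnostic object to PNG and SVG files
#'
#' @param x any object with a `plot` method (or a function drawing a figure).
#' @param path_base file path without extension.
#' @param formats subset of `"png"`, `"svg"`.
#' @param width,height device size in inches.
#' @return the written paths, invisibly.
#' @export
render_figure <- function(x, path_base, formats = c("png", "svg"),
                          width = 8, height = 6) {
  paths <- character()
  for (fmt in formats) {
    path <- paste0(path_base, ".", fmt)
    if (fmt == "png") grDevices::png(path, width = width, height = height,
                                     units = "in", res = 150)
    else grDevices::svg(path, width = width, height = height)
    tryCatch(if (is.function(x)) x() else plot(x),
             finally = grDevices::dev.off())
    paths <- c(paths, path)
  }
  invisible(paths)
}
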