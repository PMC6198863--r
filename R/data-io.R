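#' Experimental time-course tables
#'
#' An `experiment_table` holds replicated observations of named observables in
#' arbitrary measurement units: a `time x replicate x observable` array plus
#' the time grid. Missing measurements are `NA` and are skipped (never
#' imputed) by downstream objectives.
#'
#' @param times numeric vector of measurement times (hours), sorted on
#'   construction.
#' @param values numeric array `time x replicate x observable`; the third
#'   dimension must carry observable names.
#' @param provenance free-text note on data origin.
#' @return an object of class `experiment_table`.
#' @export
experiment_table <- function(times, values, provenance = "") {
  stopifnot(is.array(values), length(dim(values)) == 3,
            dim(values)[[1]] == length(times))
  if (is.null(dimnames(values)[[3]]))
    stop("'values' must name its observables (third dimension)", call. = FALSE)
  ord <- order(times)
  times <- times[ord]
  values <- values[ord, , , drop = FALSE]
  if (anyDuplicated(times))
    stop("'times' contains duplicates", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("normalized values must be non-negative", call. = FALSE)
  if (any(apply(!is.na(values), c(1, 3), sum) < 1))
    stop("every time/observable needs at least one replicate", call. = FALSE)
  structure(list(times = times, values = values,
                 observables = dimnames(values)[[3]],
                 n_replicates = dim(values)[[2]],
                 provenance = provenance),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  cat(sprintf("Experiment table: %d times, %d replicates, observables: %s\n",
              length(x$times), x$n_replicates,
              paste(x$observables, collapse = ", ")))
  if (nzchar(x$provenance)) cat("Provenance:", x$provenance, "\n")
  invisible(x)
}

#' qPCR cycle-threshold plates
#'
#' Container for raw qPCR Ct values prior to relative quantification. Rows are
#' samples (a time point and biological replicate), columns are genes.
#'
#' @param ct numeric matrix, samples x genes, with gene column names; `NA`
#'   marks unmeasured wells.
#' @param time,replicate per-sample time (hours) and replicate index.
#' @param reference_genes character; must be a subset of the gene columns.
#' @param calibrator rule selecting calibrator samples; the default uses all
#'   baseline (`t == min(time)`) samples.
#' @return an object of class `qpcr_plate`.
#' @export
qpcr_plate <- function(ct, time, replicate, reference_genes,
                       calibrator = function(time, replicate) time == min(time)) {
  stopifnot(is.matrix(ct), nrow(ct) == length(time),
            length(replicate) == length(time))
  if (is.null(colnames(ct))) stop("'ct' needs gene column names", call. = FALSE)
  missing_ref <- setdiff(reference_genes, colnames(ct))
  if (length(missing_ref))
    stop("reference genes absent from plate: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  structure(list(ct = ct, time = time, replicate = replicate,
                 reference_genes = reference_genes, calibrator = calibrator),
            class = "qpcr_plate")
}

#' Relative quantification of qPCR plates (2^-ddCt)
#'
#' Implements the standard comparative-Ct transform: per sample, each target
#' gene's Ct is referenced to the arithmetic mean Ct of the reference genes
#' (equivalently, to the geometric mean of their expression on the linear
#' scale); the resulting dCt is then referenced to the mean dCt over the
#' calibrator samples and exponentiated, `expression = 2^-ddCt`. Samples
#' missing any reference-gene Ct are dropped with a warning.
#'
#' @param plate a [qpcr_plate()].
#' @return an [experiment_table()] of target-gene expression (fold change
#'   relative to the calibrator mean).
#' @export
ddct_normalize <- function(plate) {
  stopifnot(inherits(plate, "qpcr_plate"))
  ct <- plate$ct
  refs <- plate$reference_genes
  targets <- setdiff(colnames(ct), refs)
  ref_mean <- rowMeans(ct[, refs, drop = FALSE])
  drop <- is.na(ref_mean)
  if (any(drop)) {
    warning(sum(drop), " sample(s) dropped: missing reference-gene Ct")
    ct <- ct[!drop, , drop = FALSE]
    ref_mean <- ref_mean[!drop]
  }
  time <- plate$time[!drop]
  replicate <- plate$replicate[!drop]
  cal <- plate$calibrator(time, replicate)
  if (!any(cal)) stop("calibrator selects no samples", call. = FALSE)
  dct <- ct[, targets, drop = FALSE] - ref_mean
  cal_mean <- colMeans(dct[cal, , drop = FALSE], na.rm = TRUE)
  expr <- 2^-(sweep(dct, 2, cal_mean))

  times <- sort(unique(time))
  reps <- sort(unique(replicate))
  vals <- array(NA_real_, dim = c(length(times), length(reps), length(targets)),
                dimnames = list(NULL, NULL, targets))
  for (i in seq_along(time))
    vals[match(time[[i]], times), match(replicate[[i]], reps), ] <- expr[i, ]
  experiment_table(times, vals, provenance = "2^-ddCt normalized qPCR")
}

#' Observation maps between model species and measured observables
#'
#' The observation function is linear: `X_obs(t) = X(t) / X_SF`, where `X_SF`
#' is the per-species scale factor linking model units (e.g. nM) to arbitrary
#' measurement units.
#'
#' @param observable,species character vectors of equal length.
#' @param scale_factor positive scale factors, recycled.
#' @return a data.frame of class `observation_map`.
#' @export
observation_map <- function(observable, species, scale_factor = 100) {
  stopifnot(length(observable) == length(species), all(scale_factor > 0))
  if (anyDuplicated(observable))
    stop("each observable maps to exactly one species", call. = FALSE)
  structure(data.frame(observable = observable, species = species,
                       scale_factor = rep_len(scale_factor, length(observable)),
                       stringsAsFactors = FALSE),
            class = c("observation_map", "data.frame"))
}

#' Map a simulated time course into data units
#'
#' @param sim a `time_course` from [simulate.kinetic_model()].
#' @param map an [observation_map()].
#' @return numeric matrix time x observable in data (arbitrary) units.
#' @export
map_observation <- function(sim, map) {
  stopifnot(inherits(map, "observation_map"))
  missing_sp <- setdiff(map$species, names(sim))
  if (length(missing_sp))
    stop("species not in simulation output: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  out <- as.matrix(sim[, map$species, drop = FALSE])
  out <- sweep(out, 2, map$scale_factor, `/`)
  colnames(out) <- map$observable
  out
}

#' Replicate means and floored standard deviations
#'
#' Computes per time/observable replicate means and sample standard deviations
#' (denominator n-1). Standard deviations below the floor are replaced by it;
#' by default the floor is a fraction (5%) of the observable's mean over all
#' times, which keeps weights finite when replicates coincide.
#'
#' @param table an [experiment_table()].
#' @param sd_floor_frac floor expressed as a fraction of each observable's
#'   grand mean; set to 0 to disable flooring.
#' @return an object of class `replicate_summary` with matrices `mean`, `sd`
#'   (time x observable), a logical `floored` matrix and the floors used.
#' @export
summarize_replicates <- function(table, sd_floor_frac = 0.05) {
  stopifnot(inherits(table, "experiment_table"))
  nrep <- apply(!is.na(table$values), c(1, 3), sum)
  if (any(nrep < 2))
    stop("some time/observable cells have a single replicate; a replicate sd ",
         "cannot be formed - use unweighted mode (weighting = \"none\")",
         call. = FALSE)
  m <- apply(table$values, c(1, 3), mean, na.rm = TRUE)
  s <- apply(table$values, c(1, 3), stats::sd, na.rm = TRUE)
  floors <- sd_floor_frac * colMeans(m)
  floored <- sweep(s, 2, floors, `<`)
  s[floored] <- rep(floors, each = nrow(s))[floored]
  dimnames(m) <- dimnames(s) <- list(NULL, table$observables)
  structure(list(mean = m, sd = s, floored = floored, floors = floors,
                 times = table$times, observables = table$observables),
            class = "replicate_summary")
}

#' Read and write experiment tables as CSV
#'
#' The on-disk dialect is a plain CSV with a `time` column and one
#' `observable:rep` column per replicate (e.g. `Smad7_mRNA:1`). Rows are
#' sorted by time on read; write then read is lossless.
#'
#' @param path CSV file.
#' @return [read_experiment()] returns an [experiment_table()];
#'   `write_experiment()` returns the path invisibly.
#' @export
read_experiment <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"time" %in% names(df))
    stop("experiment CSV must have a 'time' column", call. = FALSE)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v) & v != "")
      stop(sprintf("non-numeric cell in column '%s', row %d", names(df)[[j]],
                   if (length(bad)) bad[[1]] else 1L), call. = FALSE)
    }
  }
  obs_cols <- setdiff(names(df), "time")
  if (!all(grepl(":", obs_cols, fixed = TRUE)))
    stop("replicate columns must be named 'observable:rep'", call. = FALSE)
  obs <- sub(":[^:]*$", "", obs_cols)
  rep_id <- sub("^.*:", "", obs_cols)
  observables <- unique(obs)
  reps <- unique(rep_id)
  vals <- array(NA_real_, dim = c(nrow(df), length(reps), length(observables)),
                dimnames = list(NULL, NULL, observables))
  for (j in seq_along(obs_cols))
    vals[, match(rep_id[[j]], reps), match(obs[[j]], observables)] <- df[[obs_cols[[j]]]]
  experiment_table(df$time, vals, provenance = paste("read from", path))
}

#' @rdname read_experiment
#' @param table an [experiment_table()].
#' @export
write_experiment <- function(table, path) {
  stopifnot(inherits(table, "experiment_table"))
  cols <- list(time = table$times)
  for (k in seq_along(table$observables))
    for (r in seq_len(table$n_replicates))
      cols[[paste0(table$observables[[k]], ":", r)]] <- table$values[, r, k]
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
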