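#' Compile a kinetic model to an ODE right-hand side
#'
#' Assembles the stoichiometric matrix \eqn{N} over the non-fixed species and
#' compiles the reaction rate expressions into a single vectorised function, so
#' that \eqn{dx/dt = N v(x, p)}. Fixed (`const`) species are carried in the
#' parameter vector, which lets [simulate.kinetic_model()] override them like
#' any other parameter (e.g. to change an input stimulus).
#'
#' @param model a [kinetic_model].
#' @return a list with `func(t, y, p)` (deSolve-style right-hand side returning
#'   `list(dy)`), `y0` (named initial state), `p0` (named parameters, fixed
#'   species appended), `state` (dynamic species names) and `stoich` (the
#'   stoichiometric matrix, species x reactions).
#' @export
build_odes <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  sp <- model$species
  dyn <- sp$name[!sp$fixed]
  fix <- sp$name[sp$fixed]
  p0 <- c(model$parameters, stats::setNames(sp$initial[sp$fixed], fix))
  y0 <- stats::setNames(sp$initial[!sp$fixed], dyn)

  nr <- length(model$reactions)
  N <- matrix(0, nrow = length(dyn), ncol = max(nr, 1L),
              dimnames = list(dyn, vapply(model$reactions, `[[`, "", "name")))
  for (j in seq_len(nr)) {
    rx <- model$reactions[[j]]
    for (i in seq_len(nrow(rx$reactants))) {
      s <- rx$reactants$species[[i]]
      if (s %in% dyn) N[s, j] <- N[s, j] - rx$reactants$stoich[[i]]
    }
    for (i in seq_len(nrow(rx$products))) {
      s <- rx$products$species[[i]]
      if (s %in% dyn) N[s, j] <- N[s, j] + rx$products$stoich[[i]]
    }
  }

  # substitute symbols with y[[i]] / p[[j]] references for fast evaluation
  sub_map <- c(
    lapply(seq_along(dyn), function(i) bquote(y[[.(i)]])),
    lapply(seq_along(p0), function(j) bquote(p[[.(j)]]))
  )
  names(sub_map) <- c(dyn, names(p0))
  subst <- function(e) {
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (!is.null(sub_map[[nm]])) return(sub_map[[nm]])
      return(e)
    }
    if (is.call(e)) {
      for (k in seq_along(e)[-1]) e[[k]] <- subst(e[[k]])
      return(e)
    }
    e
  }
  rate_exprs <- lapply(model$reactions, function(rx) subst(rx$rate))
  env <- new.env(parent = baseenv())
  env$N <- N
  body <- if (nr > 0) {
    vcall <- as.call(c(quote(c), rate_exprs))
    bquote({
      v <- .(vcall)
      list(as.vector(N %*% v))
    })
  } else {
    bquote(list(numeric(.(length(dyn)))))
  }
  func <- eval(call("function", as.pairlist(alist(t = , y = , p = )), body), env)

  list(func = func, y0 = y0, p0 = p0, state = dyn, fixed = fix, stoich = N)
}

#' Simulate a kinetic model
#'
#' Integrates the compiled ODE system with a stiff-capable adaptive solver
#' (deSolve's `lsoda`, which switches between Adams and BDF methods) and
#' returns the trajectory at the requested times. Initial amounts are defined
#' at \eqn{t = 0}; if the first requested time is positive the system is
#' integrated from 0 and only the requested times are reported.
#'
#' @param object a [kinetic_model].
#' @param times numeric vector of output times, strictly increasing.
#' @param parameter_overrides named numeric vector/list; names may be
#'   parameters, fixed species, or dynamic species (overriding the initial
#'   amount). The model itself is not modified.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @param maxsteps maximum internal integrator steps per output interval;
#'   exceeding it is reported as an integration failure.
#' @param compiled optional result of [build_odes()] to avoid recompilation.
#' @param nsim,seed,... ignored (present for [stats::simulate()] compatibility).
#' @return a `time_course`: a data.frame with a `time` column, one column per
#'   dynamic species and one (constant) column per fixed species.
#' @examples
#' m <- parse_model("species A = 10\nparam k = 0.1\nR1: A -> ; k*A")
#' simulate(m, times = c(0, 10))
#' @export
simulate.kinetic_model <- function(object, nsim = 1, seed = NULL,
                                   times = c(0, 1), parameter_overrides = NULL,
                                   rtol = 1e-8, atol = 1e-10, maxsteps = 5000,
                                   compiled = NULL, ...) {
  model <- object
  if (length(times) == 0 || is.unsorted(times, strictly = TRUE))
    stop("'times' must be non-empty and strictly increasing", call. = FALSE)
  sys <- if (is.null(compiled)) build_odes(model) else compiled
  y0 <- sys$y0
  p <- sys$p0
  if (length(parameter_overrides)) {
    ov <- unlist(parameter_overrides)
    unknown <- setdiff(names(ov), c(names(p), names(y0)))
    if (length(unknown))
      stop("override names unknown to the model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    ip <- intersect(names(ov), names(p))
    p[ip] <- ov[ip]
    iy <- intersect(names(ov), names(y0))
    y0[iy] <- ov[iy]
  }

  tgrid <- times
  if (times[[1]] > 0) tgrid <- c(0, times)
  if (length(tgrid) == 1L || max(tgrid) == tgrid[[1]]) {
    out <- matrix(y0, nrow = length(times), ncol = length(y0), byrow = TRUE,
                  dimnames = list(NULL, names(y0)))
  } else {
    sol <- tryCatch(
      suppressWarnings(deSolve::lsoda(y = y0, times = tgrid, func = sys$func,
                                      parms = p, rtol = rtol, atol = atol,
                                      maxsteps = maxsteps)),
      error = function(e) e)
    ok <- !inherits(sol, "error") && nrow(sol) == length(tgrid) &&
      !anyNA(sol[, -1, drop = FALSE]) && all(is.finite(sol[, -1]))
    if (!ok) {
      t_fail <- if (inherits(sol, "error")) NA_real_ else tgrid[nrow(sol)]
      stop(sprintf(
        "integration of model '%s' failed near t = %s (parameters: %s)",
        model$name, format(t_fail),
        paste(sprintf("%s=%.4g", names(p), p), collapse = ", ")),
        call. = FALSE)
    }
    keep <- match(times, tgrid)
    out <- sol[keep, -1, drop = FALSE]
  }
  fixcols <- matrix(p[sys$fixed], nrow = length(times), ncol = length(sys$fixed),
                    byrow = TRUE, dimnames = list(NULL, sys$fixed))
  tc <- data.frame(time = times, out, fixcols, check.names = FALSE)
  class(tc) <- c("time_course", "data.frame")
  tc
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: %d times in [%g, %g], species: %s\n",
              nrow(x), min(x$time), max(x$time),
              paste(setdiff(names(x), "time"), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Set model initial amounts from empirical baseline means
#'
#' Applies the scaled-initial rule \eqn{X(t_0) = \bar{X}(t_0) \cdot X_{SF}}:
#' the model initial amount of each mapped species is set to the empirical
#' mean of its observable at the first time point multiplied by the
#' observable's scale factor, converting arbitrary data units back to model
#' units. Unmapped species are untouched.
#'
#' @param model a [kinetic_model].
#' @param means_at_t0 named numeric: observable name -> empirical mean at t0
#'   (arbitrary units).
#' @param map an [observation_map()] linking observables to species and scale
#'   factors.
#' @return a new `kinetic_model` with updated initial amounts.
#' @export
set_scaled_initials <- function(model, means_at_t0, map) {
  stopifnot(inherits(model, "kinetic_model"), inherits(map, "observation_map"))
  for (obs in names(means_at_t0)) {
    row <- match(obs, map$observable)
    if (is.na(row))
      stop("observable '", obs, "' is not in the observation map", call. = FALSE)
    sp <- map$species[[row]]
    i <- match(sp, model$species$name)
    if (is.na(i))
      stop("mapped species '", sp, "' is not in the model", call. = FALSE)
    model$species$initial[[i]] <- means_at_t0[[obs]] * map$scale_factor[[row]]
  }
  model
}
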