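#' Define a parameter-estimation problem
#'
#' Binds a kinetic model, replicated experimental data, an observation map and
#' a set of free parameters with box bounds into a single fit problem. The
#' objective minimised by the optimizers is the weighted residual sum of
#' squares over every replicate data point,
#' \deqn{RSS = \sum_{t,o,r} \left(\frac{y_{tor} - X_o(t)/X_{SF,o}}{\sigma_{to}}\right)^2,}
#' with \eqn{\sigma_{to}} the (floored) replicate standard deviation at that
#' time and observable, or 1 in unweighted mode. Missing points are skipped.
#'
#' @param model a [kinetic_model].
#' @param data an [experiment_table()].
#' @param map an [observation_map()] covering every data observable.
#' @param free free-parameter specification: a character vector of model
#'   parameter names (given the default bounds), or a data.frame with columns
#'   `name`, `lower`, `upper`.
#' @param lower,upper default box bounds applied when `free` is a character
#'   vector.
#' @param weighting `"sd"` (replicate-sd weights) or `"none"`.
#' @param sd_floor_frac passed to [summarize_replicates()].
#' @param rtol,atol,maxsteps integrator settings used when evaluating the
#'   objective. Estimation evaluates the model at wildly varying parameter
#'   sets, so these default looser than [simulate.kinetic_model()]'s
#'   reporting tolerances; residual tolerancing error is far below the
#'   measurement noise the objective weighs against.
#' @return an object of class `fit_problem`.
#' @export
fit_problem <- function(model, data, map, free,
                        lower = 1e-7, upper = 1e4,
                        weighting = c("sd", "none"), sd_floor_frac = 0.05,
                        rtol = 1e-6, atol = 1e-8, maxsteps = 2000) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(model, "kinetic_model"), inherits(data, "experiment_table"),
            inherits(map, "observation_map"))
  if (is.character(free))
    free <- data.frame(name = free, lower = lower, upper = upper,
                       stringsAsFactors = FALSE)
  stopifnot(all(c("name", "lower", "upper") %in% names(free)))
  if (!all(free$lower > 0 & free$lower < free$upper))
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  bad <- setdiff(free$name, names(model$parameters))
  if (length(bad))
    stop("free parameters not in the model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  unmapped <- setdiff(data$observables, map$observable)
  if (length(unmapped))
    stop("data observables without an observation map entry: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  map <- map[match(data$observables, map$observable), , drop = FALSE]
  class(map) <- c("observation_map", "data.frame")

  summary <- NULL
  if (weighting == "sd")
    summary <- summarize_replicates(data, sd_floor_frac)
  sigma <- if (weighting == "sd") summary$sd else
    matrix(1, length(data$times), length(data$observables))

  structure(list(model = model, data = data, map = map, free = free,
                 weighting = weighting, summary = summary, sigma = sigma,
                 compiled = build_odes(model),
                 rtol = rtol, atol = atol, maxsteps = maxsteps,
                 n_points = sum(!is.na(data$values))),
            class = "fit_problem")
}

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf(
    "Fit problem: model '%s', %d free parameters, %d data points (%s-weighted)\n",
    x$model$name, nrow(x$free), x$n_points, x$weighting))
  print(x$free, row.names = FALSE)
  invisible(x)
}

#' Build the objective function of a fit problem
#'
#' Returns a closure mapping a free-parameter vector (linear scale, ordered as
#' `problem$free$name`) to the weighted RSS. Failed integrations return `Inf`
#' (counted on the closure's environment as `n_failures`) so that stochastic
#' search can continue.
#'
#' @param problem a [fit_problem()].
#' @param fixed optional named numeric of parameters to pin at given values
#'   (removed from the free set), used by profile likelihoods.
#' @return a function `f(values) -> rss` with attribute `free_names`.
#' @export
make_objective <- function(problem, fixed = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  free_names <- setdiff(problem$free$name, names(fixed))
  sys <- problem$compiled
  times <- problem$data$times
  Y <- problem$data$values
  sigma <- problem$sigma
  map <- problem$map
  model <- problem$model
  n_obs <- length(problem$data$observables)
  fixed <- unlist(fixed)
  n_failures <- 0L

  f <- function(values) {
    ov <- c(stats::setNames(as.numeric(values), free_names), fixed)
    tc <- tryCatch(
      simulate(model, times = times, parameter_overrides = ov, compiled = sys,
               rtol = problem$rtol, atol = problem$atol,
               maxsteps = problem$maxsteps),
      error = function(e) NULL)
    if (is.null(tc)) {
      n_failures <<- n_failures + 1L
      return(Inf)
    }
    sim_obs <- map_observation(tc, map)
    rss <- 0
    for (k in seq_len(n_obs)) {
      r <- (Y[, , k] - sim_obs[, k]) / sigma[, k]
      rss <- rss + sum(r * r, na.rm = TRUE)
    }
    rss
  }
  attr(f, "free_names") <- free_names
  f
}

#' Weighted residual sum of squares at given parameter values
#'
#' @param problem a [fit_problem()].
#' @param values named numeric of free-parameter values (any order; all free
#'   parameters must be present).
#' @return the weighted RSS (scalar; `Inf` if the integration fails).
#' @export
weighted_rss <- function(problem, values) {
  f <- make_objective(problem)
  nm <- attr(f, "free_names")
  if (!all(nm %in% names(values)))
    stop("missing values for free parameters: ",
         paste(setdiff(nm, names(values)), collapse = ", "), call. = FALSE)
  f(values[nm])
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Draw random starting values, log-uniform within bounds
#'
#' Each free parameter is drawn log-uniformly on its `[lower, upper]`
#' interval, the standard choice when bounds span many decades.
#'
#' @param problem a [fit_problem()].
#' @param seed optional integer seed (the global RNG state is restored).
#' @return named numeric of starting values.
#' @export
sample_start <- function(problem, seed = NULL) {
  with_seed(seed, {
    lo <- log10(problem$free$lower)
    hi <- log10(problem$free$upper)
    stats::setNames(10^stats::runif(length(lo), lo, hi), problem$free$name)
  })
}

#' Optimizer configurations
#'
#' Settings for the two optimizers. The genetic algorithm is a real-coded GA
#' operating in log10-parameter space: tournament selection (size 2), uniform
#' crossover, per-gene Gaussian mutation (sd in decades), elitism of one.
#' Hooke-Jeeves is a bound-clipped pattern search, also in log10 space, with
#' step halving; it terminates when the step falls below `tolerance` (decades)
#' or after `iteration_limit` exploratory iterations.
#'
#' @param algorithm `"genetic"` or `"hooke_jeeves"`.
#' @param population_size,generations GA population and generation counts.
#' @param mutation_rate per-gene mutation probability (default `1/d`).
#' @param crossover_rate probability that an offspring is produced by uniform
#'   crossover rather than copied from its first parent.
#' @param mutation_sd mutation standard deviation in decades.
#' @param tolerance,iteration_limit Hooke-Jeeves termination settings.
#' @param step0 initial Hooke-Jeeves step in decades.
#' @param seed optional integer seed.
#' @return a list of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("genetic", "hooke_jeeves"),
                             population_size = 300, generations = 500,
                             mutation_rate = NULL, crossover_rate = 0.5,
                             mutation_sd = 0.2,
                             tolerance = 1e-6, iteration_limit = 50,
                             step0 = 0.5, seed = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(population_size >= 2, generations >= 1, tolerance > 0,
            iteration_limit >= 1)
  structure(list(algorithm = algorithm, population_size = population_size,
                 generations = generations, mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate, mutation_sd = mutation_sd,
                 tolerance = tolerance, iteration_limit = iteration_limit,
                 step0 = step0, seed = seed),
            class = "optimizer_config")
}

new_parameter_set <- function(values, rss, run_id = NA_integer_, seed = NA_integer_,
                              algorithm = NA_character_, chased = FALSE) {
  structure(list(values = values, rss = rss, run_id = run_id, seed = seed,
                 algorithm = algorithm, chased = chased),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("Parameter set (run %s, %s%s): RSS = %.6g\n",
              x$run_id, x$algorithm, if (isTRUE(x$chased)) ", chased" else "",
              x$rss))
  print(x$values)
  invisible(x)
}

#' Genetic-algorithm global search
#'
#' Minimises `objective` within box bounds using a real-coded genetic
#' algorithm in log10-parameter space (see [optimizer_config()] for the
#' operators). The best-so-far objective value is non-increasing across
#' generations (elitism); aborts if the whole population evaluates to `Inf`
#' for three consecutive generations.
#'
#' @param objective function of a linear-scale parameter vector.
#' @param lower,upper bounds (linear scale).
#' @param config an [optimizer_config()].
#' @return a `parameter_set` with an additional `trace` element (best RSS per
#'   generation).
#' @export
genetic_algorithm <- function(objective, lower, upper, config = optimizer_config()) {
  d <- length(lower)
  lo <- log10(lower); hi <- log10(upper)
  np <- config$population_size
  pmut <- if (is.null(config$mutation_rate)) 1 / d else config$mutation_rate
  with_seed(config$seed, {
    pop <- matrix(stats::runif(np * d, lo, hi), nrow = d)
    fit <- apply(pop, 2, function(x) objective(10^x))
    best_i <- which.min(fit)
    best_x <- pop[, best_i]; best_f <- fit[best_i]
    trace <- numeric(config$generations)
    bad_gens <- 0L
    for (g in seq_len(config$generations)) {
      newpop <- matrix(0, d, np)
      newpop[, 1] <- best_x                      # elitism
      for (j in 2:np) {
        pick <- function() {
          ij <- sample.int(np, 2)
          if (fit[ij[1]] <= fit[ij[2]]) pop[, ij[1]] else pop[, ij[2]]
        }
        p1 <- pick()
        child <- p1
        if (stats::runif(1) < config$crossover_rate) {
          p2 <- pick()
          take2 <- stats::runif(d) < 0.5
          child[take2] <- p2[take2]
        }
        mut <- stats::runif(d) < pmut
        if (any(mut))
          child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, config$mutation_sd)
        newpop[, j] <- pmin(pmax(child, lo), hi)
      }
      pop <- newpop
      fit <- apply(pop, 2, function(x) objective(10^x))
      if (all(!is.finite(fit))) {
        bad_gens <- bad_gens + 1L
        if (bad_gens >= 3L)
          stop("genetic algorithm aborted: entire population infeasible for 3 ",
               "consecutive generations", call. = FALSE)
      } else bad_gens <- 0L
      gi <- which.min(fit)
      if (fit[gi] < best_f) { best_f <- fit[gi]; best_x <- pop[, gi] }
      trace[g] <- best_f
    }
    ps <- new_parameter_set(stats::setNames(10^best_x, names(lower)), best_f,
                            seed = if (is.null(config$seed)) NA_integer_
                                   else config$seed,
                            algorithm = "genetic")
    ps$trace <- trace
    ps
  })
}

#' Hooke-Jeeves pattern search
#'
#' Bound-clipped pattern search in log10-parameter space: an exploratory probe
#' of +/- one step per coordinate, followed by a pattern move along the
#' accepted direction; the step is halved whenever the exploratory phase fails
#' to improve. Terminates when the step falls below `tolerance` or the
#' iteration limit is reached. The returned objective value never exceeds the
#' value at `start`.
#'
#' @param objective function of a linear-scale parameter vector.
#' @param lower,upper bounds (linear scale).
#' @param start named starting values within bounds.
#' @param config an [optimizer_config()]; `tolerance`, `iteration_limit` and
#'   `step0` are used.
#' @return a `parameter_set`.
#' @export
hooke_jeeves <- function(objective, lower, upper, start,
                         config = optimizer_config(algorithm = "hooke_jeeves")) {
  lo <- log10(lower); hi <- log10(upper)
  x <- pmin(pmax(log10(as.numeric(start)), lo), hi)
  fx <- objective(10^x)
  d <- length(x)

  explore <- function(x, fx, s) {
    for (i in seq_len(d)) {
      for (dir in c(1, -1)) {
        xi <- x
        xi[i] <- min(max(xi[i] + dir * s, lo[i]), hi[i])
        if (xi[i] == x[i]) next
        fi <- objective(10^xi)
        if (fi < fx) { x <- xi; fx <- fi; break }
      }
    }
    list(x = x, f = fx)
  }

  s <- config$step0
  iter <- 0L
  while (s >= config$tolerance && iter < config$iteration_limit) {
    iter <- iter + 1L
    ex <- explore(x, fx, s)
    if (ex$f < fx) {
      # pattern move: extrapolate along the successful direction
      repeat {
        xp <- pmin(pmax(ex$x + (ex$x - x), lo), hi)
        x <- ex$x; fx <- ex$f
        fp <- objective(10^xp)
        ex <- explore(xp, fp, s)
        if (ex$f >= fx) break
      }
    } else {
      s <- s / 2
    }
  }
  new_parameter_set(stats::setNames(10^x, names(start)), fx,
                    algorithm = "hooke_jeeves")
}
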