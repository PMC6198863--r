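# Shared fixtures, all built in code.

# one-species exponential decay, truth k = 0.1, X(0) = 10
decay_model <- function() {
  parse_model("
model decay
species X = 10
param k = 0.1
deg: X -> ; k*X
end")
}

# two parameters entering the dynamics only through their product k1*k2
product_model <- function() {
  parse_model("
model product_coupled
species A = 10
param k1 = 0.5
param k2 = 0.2
deg: A -> ; k1*k2*A
end")
}

# replicated table from a model's exact trajectory (identity-scale map)
exact_table <- function(model, map, times = c(0, 1, 2, 4, 8, 12),
                        replicates = 3) {
  generate_data(model, times = times, replicates = replicates,
                noise = "none", map = map, seed = 1)
}

decay_map <- function(scale_factor = 1)
  observation_map("X_obs", "X", scale_factor)

# reporting-accuracy tolerances so that noise-free data from the generator
# evaluates to an exactly-zero objective at the truth
decay_problem <- function(weighting = "sd", times = c(0, 1, 2, 4, 8, 12),
                          replicates = 3, sf = 1) {
  m <- decay_model()
  fit_problem(m, exact_table(m, decay_map(sf), times, replicates),
              decay_map(sf), free = "k", weighting = weighting,
              rtol = 1e-8, atol = 1e-10)
}

product_problem <- function() {
  m <- product_model()
  map <- observation_map("A_obs", "A", 1)
  fit_problem(m, exact_table(m, map), map, free = c("k1", "k2"),
              rtol = 1e-8, atol = 1e-10)
}

# brute-force reference objective: naive triple loop over time, observable,
# replicate -- the independent oracle for the weighted RSS
oracle_rss <- function(problem, values) {
  tc <- simulate(problem$model, times = problem$data$times,
                 parameter_overrides = values,
                 rtol = problem$rtol, atol = problem$atol,
                 maxsteps = problem$maxsteps)
  total <- 0
  for (it in seq_along(problem$data$times)) {
    for (k in seq_along(problem$data$observables)) {
      row <- match(problem$data$observables[[k]], problem$map$observable)
      sim <- tc[[problem$map$species[[row]]]][[it]] / problem$map$scale_factor[[row]]
      for (r in seq_len(problem$data$n_replicates)) {
        y <- problem$data$values[it, r, k]
        if (is.na(y)) next
        total <- total + ((y - sim) / problem$sigma[it, k])^2
      }
    }
  }
  total
}

# an archive with prescribed RSS values and parameter columns, for testing
# ranking/diagnostics independently of any optimization run
fake_archive <- function(problem, rss, params = NULL) {
  n <- length(rss)
  pn <- problem$free$name
  sets <- data.frame(run_id = seq_len(n), seed = seq_len(n),
                     algorithm = "genetic", chased = FALSE,
                     source_id = NA_integer_, rss = rss,
                     stringsAsFactors = FALSE)
  if (is.null(params))
    params <- matrix(1, n, length(pn), dimnames = list(NULL, pn))
  for (p in pn) sets[[p]] <- params[, p]
  odecal:::rank_archive(odecal:::new_estimation_archive(problem, sets))
}

reduced_ga <- function(pop = 24, gens = 40)
  optimizer_config(population_size = pop, generations = gens)

quick_hj <- function(tol = 1e-8, iters = 200)
  optimizer_config(algorithm = "hooke_jeeves", tolerance = tol,
                   iteration_limit = iters)
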