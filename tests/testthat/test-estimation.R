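test_that("weighted RSS matches hand arithmetic and the brute-force oracle", {
  # perfect fit: data generated noise-free from the model at the truth
  prob <- decay_problem()
  expect_lt(weighted_rss(prob, c(k = 0.1)), 1e-10)

  # one point, y = 5, sim = 3: sigma 1 gives 4, sigma 2 gives 1
  m <- parse_model("species C = 3\nparam q = 1")
  vals <- array(5, c(1, 1, 1), dimnames = list(NULL, NULL, "C_obs"))
  tab <- experiment_table(0, vals)
  p1 <- fit_problem(m, tab, observation_map("C_obs", "C", 1), free = "q",
                    weighting = "none")
  expect_equal(weighted_rss(p1, c(q = 1)), 4)
  p2 <- p1
  p2$sigma[] <- 2
  expect_equal(weighted_rss(p2, c(q = 1)), 1)

  # oracle equivalence on random parameter values, with missing points
  m2 <- motif_models()$negative_feedback
  dat <- generate_data(m2, noise = "gaussian_cv", cv = 0.1,
                       map = motif_observation_map(), seed = 3)
  dat$values[2, 4, 1] <- NA
  dat$values[5, 1, 2] <- NA
  prob2 <- fit_problem(m2, dat, motif_observation_map(),
                       free = c("k1", "k2", "k3"))
  set.seed(11)
  for (i in 1:10) {
    v <- sample_start(prob2)
    got <- weighted_rss(prob2, v)
    ref <- oracle_rss(prob2, v)
    expect_lt(abs(got - ref) / ref, 1e-12)
  }
})

test_that("random starts are log-uniform, in-bounds and seeded", {
  prob <- decay_problem()
  prob$free$lower <- 1e-7
  prob$free$upper <- 1e4
  draws <- replicate(5000, sample_start(prob, seed = NULL))
  expect_true(all(draws >= 1e-7 & draws <= 1e4))
  # midpoint of log10-bounds [-7, 4] is -1.5
  expect_lt(abs(median(log10(draws)) - (-1.5)), 0.15)
  expect_identical(sample_start(prob, seed = 99), sample_start(prob, seed = 99))
})

test_that("integration failures yield an infinite objective, not an error", {
  m <- parse_model("species X = 1\nparam k = 1\nR1: -> X ; exp(k*X)")
  tab <- exact_table(decay_model(), decay_map())
  dimnames(tab$values)[[3]] <- "X_obs"
  prob <- fit_problem(m, tab, observation_map("X_obs", "X", 1), free = "k",
                      lower = 1, upper = 1e4)
  f <- make_objective(prob)
  expect_identical(f(1e3), Inf)
  expect_gt(environment(f)$n_failures, 0)
})

test_that("the genetic algorithm converges on a quadratic bowl, monotonically", {
  xstar <- c(a = 0.02, b = 3)
  obj <- function(x) sum((x - xstar)^2)
  lo <- c(a = 1e-7, b = 1e-7); hi <- c(a = 1e4, b = 1e4)
  ps <- genetic_algorithm(obj, lo, hi,
                          optimizer_config(population_size = 40,
                                           generations = 60, seed = 5))
  expect_lt(ps$rss, 1e-2)
  expect_false(is.unsorted(rev(ps$trace)))    # best-so-far non-increasing
  ps2 <- genetic_algorithm(obj, lo, hi,
                           optimizer_config(population_size = 40,
                                            generations = 60, seed = 5))
  expect_identical(ps$values, ps2$values)     # seeded determinism
  expect_identical(ps$trace, ps2$trace)
})

test_that("the genetic algorithm aborts on a persistently infeasible problem", {
  expect_error(
    genetic_algorithm(function(x) Inf, c(a = 1e-7), c(a = 1e4),
                      optimizer_config(population_size = 5, generations = 10,
                                       seed = 1)),
    "infeasible")
})

test_that("Hooke-Jeeves refines to the optimum and never worsens the start", {
  xstar <- c(a = 1, b = 2)
  obj <- function(x) sum((x - xstar)^2)
  lo <- c(a = 1e-7, b = 1e-7); hi <- c(a = 1e4, b = 1e4)
  ps <- hooke_jeeves(obj, lo, hi, c(a = 20, b = 0.05),
                     optimizer_config(algorithm = "hooke_jeeves",
                                      tolerance = 1e-10,
                                      iteration_limit = 1000))
  expect_lt(max(abs(ps$values - xstar)), 1e-6)

  # started at the optimum it returns unchanged values
  ps0 <- hooke_jeeves(obj, lo, hi, xstar, quick_hj())
  expect_equal(ps0$values, xstar, tolerance = 1e-7)

  # monotonicity on arbitrary instances
  set.seed(8)
  for (i in 1:5) {
    start <- 10^runif(2, -3, 3); names(start) <- c("a", "b")
    ps_i <- hooke_jeeves(obj, lo, hi, start,
                         optimizer_config(algorithm = "hooke_jeeves",
                                          tolerance = 1e-4,
                                          iteration_limit = 10))
    expect_lte(ps_i$rss, obj(start))
  }
})

test_that("repeat estimations are scheduling-independent and seed-nested", {
  prob <- decay_problem()
  cfg <- optimizer_config(algorithm = "hooke_jeeves", tolerance = 1e-4,
                          iteration_limit = 30)
  a1 <- calibrate(prob, n_runs = 6, config = cfg, seed = 10, max_workers = 1)
  expect_equal(nrow(a1$sets), 6)
  expect_true(a1$ranked)
  expect_false(is.unsorted(a1$sets$rss))
  a4 <- calibrate(prob, n_runs = 6, config = cfg, seed = 10, max_workers = 4)
  expect_equal(sort(a4$sets$rss), sort(a1$sets$rss))
  expect_equal(a4$sets, a1$sets)   # ranked order ties broken by run id

  # nested seed prefixes: min RSS over n runs is non-increasing in n
  a3 <- calibrate(prob, n_runs = 3, config = cfg, seed = 10)
  expect_lte(min(a1$sets$rss), min(a3$sets$rss))
})

test_that("chaser refines the selected sets and flags them", {
  prob <- decay_problem()
  cfg <- optimizer_config(algorithm = "hooke_jeeves", tolerance = 1e-2,
                          iteration_limit = 5)   # deliberately coarse runs
  a <- calibrate(prob, n_runs = 5, config = cfg, seed = 2)
  a2 <- chaser(a, top_k = 3, config = quick_hj(tol = 1e-10, iters = 500))
  expect_equal(nrow(a2$sets), 8)
  expect_equal(sum(a2$sets$chased), 3)
  for (i in which(a2$sets$chased)) {
    src <- a2$sets$rss[match(a2$sets$source_id[[i]], a2$sets$run_id)]
    expect_lte(a2$sets$rss[[i]], src)
  }
  # chasing an already-local optimum leaves values unchanged within tolerance
  best <- coef(a2)
  a3 <- chaser(a2, top_k = 1, config = quick_hj(tol = 1e-10, iters = 500))
  expect_equal(coef(a3), best, tolerance = 1e-6)
  # over-large selection is clipped with a warning
  expect_warning(chaser(a, top_k = 99,
                        config = quick_hj(tol = 1e-2, iters = 3)), "clipped")
})

test_that("ranking and truncation subset archives as specified", {
  prob <- decay_problem()
  a <- fake_archive(prob, rss = c(5, 1, 3, 2, 4))
  expect_equal(a$sets$rss, 1:5)
  expect_equal(nrow(truncate_archive(a, "fraction", 0.4)$sets), 2)
  expect_equal(truncate_archive(a, "count", 99)$sets, a$sets)  # clipped
  expect_equal(nrow(truncate_archive(a, "rss_cutoff", min(a$sets$rss))$sets), 1)
  expect_error(truncate_archive(a, "fraction", 1.2), "fraction")
  # 300 sets at the demo's top-10% truncation keep exactly 30
  big <- fake_archive(prob, rss = rev(seq_len(300)))
  expect_equal(nrow(truncate_archive(big, "fraction", 0.10)$sets), 30)
})

test_that("archive methods expose the fitted model", {
  prob <- decay_problem()
  a <- calibrate(prob, n_runs = 2, config = quick_hj(tol = 1e-8, iters = 100),
                 seed = 4)
  expect_named(coef(a), "k")
  expect_lt(abs(coef(a)[["k"]] - 0.1) / 0.1, 0.01)
  pr <- predict(a, times = c(0, 1, 2))
  expect_named(pr, c("time", "X_obs"))
  res <- residuals(a)
  expect_equal(dim(res), dim(prob$data$values))
  expect_lt(max(abs(res)), 1e-2)
  s <- summary(a)
  expect_s3_class(s, "summary.estimation_archive")
  # CSV persistence round-trips
  path <- withr::local_tempfile(fileext = ".csv")
  write_archive(a, path)
  a2 <- read_archive(path, prob)
  expect_equal(a2$sets$rss, a$sets$rss)
  expect_equal(a2$sets$k, a$sets$k)
})
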