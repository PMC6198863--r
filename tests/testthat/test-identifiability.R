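# construct a profile_curve directly from a known RSS shape
synthetic_curve <- function(parameter = "k", best_value = 1, best_rss = 2,
                            shape = function(d) d^2, span = 3, n = 41) {
  lx <- seq(-span, span, length.out = n)
  pts <- data.frame(value = best_value * 10^lx, rss = best_rss + shape(lx))
  structure(list(parameter = parameter, best_value = best_value,
                 best_rss = best_rss, points = pts, span_orders = span,
                 n_points = (n - 1) / 2, local_config = NULL,
                 source_id = NA_integer_),
            class = "profile_curve")
}

test_that("confidence thresholds follow the likelihood-ratio closed forms", {
  th <- confidence_threshold(10, alpha = 0.95)
  expect_equal(th$value, 10 + qchisq(0.95, 1))
  # alpha -> 0+ collapses the threshold onto the best RSS
  expect_lt(confidence_threshold(10, alpha = 1e-12)$value - 10, 1e-10)
  # F-based mode converges to the chi-squared offset for n >> p when the
  # best RSS scales as its expectation n - p
  n <- 1e6
  thf <- confidence_threshold(n - 3, alpha = 0.95, mode = "f_based",
                              n_points_total = n, n_free = 3)
  expect_equal(thf$value - (n - 3), qchisq(0.95, 1), tolerance = 1e-3)
  expect_error(confidence_threshold(10, mode = "f_based",
                                    n_points_total = 3, n_free = 5), "n > p")
})

test_that("profile classification implements the three-way rule", {
  # parabola in log space crossing on both sides: identifiable, and the
  # spline-located crossings match the analytic ones
  a <- 2
  cv <- synthetic_curve(shape = function(d) a * d^2)
  thr <- confidence_threshold(cv$best_rss, alpha = 0.95)
  cl <- classify_profile(cv, thr)
  expect_equal(cl$classification, "identifiable")
  d_star <- sqrt(qchisq(0.95, 1) / a)
  expect_equal(log10(cl$ci_upper), d_star, tolerance = 0.01)
  expect_equal(log10(cl$ci_lower), -d_star, tolerance = 0.01)

  # flat curve: structurally non-identifiable, unbounded CI, flagged suspected
  flat <- synthetic_curve(shape = function(d) 0 * d)
  clf <- classify_profile(flat, thr)
  expect_equal(clf$classification, "structurally_non_identifiable")
  expect_identical(c(clf$ci_lower, clf$ci_upper), c(-Inf, Inf))
  expect_true(clf$suspected)

  # curve rising only above the best value: practical, finite upper bound only
  one_sided <- synthetic_curve(shape = function(d) pmax(d, 0)^2 * 5)
  clo <- classify_profile(one_sided, thr)
  expect_equal(clo$classification, "practically_non_identifiable")
  expect_identical(clo$ci_lower, -Inf)
  expect_true(is.finite(clo$ci_upper))

  expect_error(classify_profile(cv, cv$best_rss - 1), "threshold")
})

test_that("classification is stable under scan refinement and rescaling", {
  a <- 1.3
  thr <- confidence_threshold(2, alpha = 0.95)
  coarse <- classify_profile(synthetic_curve(shape = function(d) a * d^2,
                                             n = 21), thr)
  fine <- classify_profile(synthetic_curve(shape = function(d) a * d^2,
                                           n = 41), thr)
  expect_lt(abs(fine$ci_upper - coarse$ci_upper) / fine$ci_upper, 0.02)
  expect_lt(abs(fine$ci_lower - coarse$ci_lower) / fine$ci_lower, 0.02)
  # multiplying the profiled parameter by a constant shifts the CI by the
  # same factor and leaves the classification unchanged
  scaled <- synthetic_curve(best_value = 50, shape = function(d) a * d^2)
  cls <- classify_profile(scaled, thr)
  base <- classify_profile(synthetic_curve(shape = function(d) a * d^2), thr)
  expect_equal(cls$classification, base$classification)
  expect_equal(cls$ci_upper / 50, base$ci_upper, tolerance = 1e-6)
})

test_that("a 1-parameter exponential fit profiles as identifiable", {
  prob <- decay_problem()
  cv <- profile_likelihood(prob, c(k = 0.1), "k", span_orders = 2,
                           n_points = 10)
  # the point nearest the best value reproduces the best RSS
  i0 <- which.min(abs(log10(cv$points$value / 0.1)))
  expect_lt(cv$points$rss[[i0]], 1e-8)
  # RSS grows strictly away from the truth in both directions
  below <- cv$points$rss[cv$points$value < 0.1]
  above <- cv$points$rss[cv$points$value > 0.1]
  expect_false(is.unsorted(rev(below), strictly = TRUE))
  expect_false(is.unsorted(above, strictly = TRUE))
  thr <- confidence_threshold(cv$best_rss, alpha = 0.95)
  cl <- classify_profile(cv, thr)
  expect_equal(cl$classification, "identifiable")
  expect_true(cl$ci_lower < 0.1 && cl$ci_upper > 0.1)
})

test_that("a product-coupled pair is structurally flat with a -1 log-log trace", {
  prob <- product_problem()
  best <- c(k1 = 0.5, k2 = 0.2)
  cv <- profile_likelihood(prob, best, "k1", span_orders = 2, n_points = 8,
                           local_config = quick_hj(tol = 1e-8, iters = 200))
  expect_lt(max(cv$points$rss) - min(cv$points$rss), 1e-6)
  thr <- confidence_threshold(cv$best_rss, alpha = 0.95)
  expect_equal(classify_profile(cv, thr)$classification,
               "structurally_non_identifiable")
  # co-parameter trace: log k2 = log c - log k1
  tr <- coparameter_trace(cv, "k2")
  expect_equal(nrow(tr), nrow(cv$points))
  fit <- lm(log10(other) ~ log10(value), data = tr)
  # the fit is essentially exact by construction; summary.lm warns about it
  fs <- suppressWarnings(summary(fit))
  expect_gt(fs$r.squared, 0.999)
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.01)
  expect_error(coparameter_trace(cv, "k1"), "co-parameter")
})

test_that("profile_all reports every parameter for every starting set", {
  # k1 identifiable; k2, k3 a structural product pair
  m <- parse_model("
model mixed
species A = 10
species B = 0
param k1 = 0.3
param k2 = 0.5
param k3 = 0.2
R1: A -> B ; k1*A
R2: B -> ; k2*k3*B
end")
  map <- observation_map(c("A_obs", "B_obs"), c("A", "B"), 1)
  dat <- exact_table(m, map)
  prob <- fit_problem(m, dat, map, free = c("k1", "k2", "k3"))
  truth <- c(k1 = 0.3, k2 = 0.5, k3 = 0.2)
  sets <- list(odecal:::new_parameter_set(truth, weighted_rss(prob, truth),
                                          run_id = 1L),
               odecal:::new_parameter_set(truth, weighted_rss(prob, truth),
                                          run_id = 2L))
  rep <- profile_all(prob, sets, span_orders = 1.5, n_points = 6,
                     local_config = quick_hj(tol = 1e-8, iters = 150))
  expect_equal(nrow(rep$table), 2 * 3)   # sets x parameters
  tab1 <- rep$table[rep$table$set_id == 1, ]
  cls <- setNames(tab1$classification, tab1$parameter)
  expect_equal(unname(cls["k1"]), "identifiable")
  expect_equal(unname(cls["k2"]), "structurally_non_identifiable")
  expect_equal(unname(cls["k3"]), "structurally_non_identifiable")
  # identical starting sets give identical reports
  t2 <- rep$table[rep$table$set_id == 2, ]
  expect_equal(t2$classification, tab1$classification)
  expect_equal(t2$ci_lower, tab1$ci_lower)
  expect_length(rep$discordant, 0)
})

test_that("profile confidence intervals achieve near-nominal coverage", {
  # 1-parameter exponential decay, Gaussian noise with known sd: the
  # sd-weighted RSS is a chi-squared statistic, so the 95% profile CI
  # should cover the true rate in about 95% of repetitions
  m <- decay_model()
  map <- decay_map()
  times <- c(0, 1, 2, 4, 8, 12)
  truth <- simulate(m, times = times)$X
  sigma0 <- 0.3
  n_rep <- 200
  covered <- logical(n_rep)
  set.seed(2024)
  for (r in seq_len(n_rep)) {
    vals <- array(truth + rnorm(6 * 6, 0, sigma0), c(6, 6, 1),
                  dimnames = list(NULL, NULL, "X_obs"))
    vals[vals < 0] <- 0
    prob <- fit_problem(m, experiment_table(times, vals), map, free = "k",
                        weighting = "none")
    prob$sigma[] <- sigma0                       # known error scale
    obj <- make_objective(prob)
    opt <- optimize(function(l) obj(10^l), c(-3, 1), tol = 1e-9)
    best <- c(k = 10^opt$minimum)
    cv <- profile_likelihood(prob, best, "k", span_orders = 1, n_points = 12)
    cl <- classify_profile(cv, confidence_threshold(opt$objective, 0.95))
    covered[r] <- cl$ci_lower <= 0.1 && 0.1 <= cl$ci_upper
  }
  # binomial tolerance: 0.95 +/- 3 * sqrt(0.95 * 0.05 / 200)
  expect_gt(mean(covered), 0.95 - 3 * sqrt(0.95 * 0.05 / n_rep))
  expect_lte(mean(covered), 1)
})
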