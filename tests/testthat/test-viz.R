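test_that("likelihood-ranks output is sorted and shows minima as plateaus", {
  prob <- decay_problem()
  lr <- likelihood_ranks(fake_archive(prob, rss = c(9, 2, 5, 2, 9, 5)))
  expect_false(is.unsorted(lr$data$rss))
  expect_equal(lr$data$rank, 1:6)

  # all-equal RSS: the flat line of a single repeatedly-found minimum
  flat <- likelihood_ranks(fake_archive(prob, rss = rep(3, 5)))
  expect_equal(unique(flat$data$rss), 3)

  # two distinct minima: two plateaus (a step function)
  two <- likelihood_ranks(fake_archive(prob, rss = rep(c(1, 10), each = 4)))
  expect_equal(rle(two$data$rss)$lengths, c(4, 4))
  expect_equal(rle(two$data$rss)$values, c(1, 10))
})

test_that("ensemble bands degenerate to the trajectory for identical sets", {
  prob <- decay_problem()
  one <- fake_archive(prob, rss = 0,
                      params = matrix(0.1, 1, 1, dimnames = list(NULL, "k")))
  et1 <- ensemble_timecourse(one, top_k = 1, times = c(0, 2, 6), n_boot = 50)
  b <- et1$bands$X_obs
  expect_equal(b$lower, b$center)
  expect_equal(b$upper, b$center)
  expect_equal(b$center, simulate(decay_model(), times = c(0, 2, 6))$X)

  # identical sets: zero-width band
  same <- fake_archive(prob, rss = rep(0, 4),
                       params = matrix(0.1, 4, 1, dimnames = list(NULL, "k")))
  et4 <- ensemble_timecourse(same, top_k = 4, times = c(0, 2, 6), n_boot = 50)
  expect_equal(et4$bands$X_obs$lower, et4$bands$X_obs$upper)

  # a spread ensemble's band contains the median trajectory
  spread <- fake_archive(prob, rss = 1:5,
                         params = matrix(c(0.05, 0.08, 0.1, 0.12, 0.2), 5, 1,
                                         dimnames = list(NULL, "k")))
  et5 <- ensemble_timecourse(spread, top_k = 5, times = c(0, 2, 6),
                             n_boot = 500, seed = 3)
  med <- apply(et5$trajectories[, , "X_obs"], 1, median)
  expect_true(all(et5$bands$X_obs$lower <= med + 1e-9))
  expect_true(all(med <= et5$bands$X_obs$upper + 1e-9))
})

test_that("parameter distributions summarize on the log scale and detect modes", {
  prob <- product_problem()
  # constant parameter: zero IQR
  const <- fake_archive(prob, rss = 1:6,
                        params = cbind(k1 = rep(0.5, 6), k2 = rep(0.2, 6)))
  pd <- param_distributions(const)
  expect_equal(pd$summaries$k1$iqr, 0)

  # bimodal parameter: two histogram modes separated by a trough
  set.seed(1)
  k1 <- c(10^rnorm(60, -2, 0.05), 10^rnorm(60, 1, 0.05))
  bi <- fake_archive(prob, rss = seq_len(120),
                     params = cbind(k1 = k1, k2 = rep(1, 120)))
  pdb <- param_distributions(bi, n_bins = 12)
  counts <- pdb$summaries$k1$counts
  peaks <- which(diff(sign(diff(c(-1, counts, -1)))) == -2)
  trough <- min(counts[seq(min(peaks), max(peaks))])
  expect_gte(length(peaks), 2)
  expect_gt(min(counts[peaks]), 2 * max(trough, 1))

  # truncation changes the summaries when the tail is biased
  tail_shift <- fake_archive(prob, rss = seq_len(100),
                             params = cbind(k1 = c(rep(0.1, 10), rep(100, 90)),
                                            k2 = rep(1, 100)))
  all_sets <- param_distributions(tail_shift)
  top10 <- param_distributions(tail_shift, truncate_mode = "fraction",
                               truncate_value = 0.10)
  expect_false(isTRUE(all.equal(all_sets$summaries$k1$median,
                                top10$summaries$k1$median)))
  expect_error(param_distributions(truncate_archive(tail_shift, "rss_cutoff",
                                                    -1)),
               "empty|archive")
})

test_that("correlation analysis flags log-linear pairs and masks degeneracies", {
  prob <- product_problem()
  # exact product coupling k1*k2 = c: r^2 = 1, slope -1 in log space
  k1 <- 10^seq(-2, 2, length.out = 20)
  cp <- fake_archive(prob, rss = seq_len(20),
                     params = cbind(k1 = k1, k2 = 0.1 / k1))
  pc <- param_correlations(cp)
  expect_equal(pc$r["k1", "k2"], -1, tolerance = 1e-12)
  expect_equal(pc$flagged$r_squared[[1]], 1, tolerance = 1e-12)

  # independent parameters: weak correlation with high probability
  set.seed(7)
  ind <- fake_archive(prob, rss = seq_len(100),
                      params = cbind(k1 = 10^runif(100, -3, 3),
                                     k2 = 10^runif(100, -3, 3)))
  pci <- param_correlations(ind)
  expect_lt(abs(pci$r["k1", "k2"]), 0.3)
  # symmetric with unit diagonal
  expect_equal(pci$r, t(pci$r))
  expect_equal(unname(diag(pci$r)), c(1, 1))

  # zero-variance parameter masked as NA
  degen <- fake_archive(prob, rss = 1:10,
                        params = cbind(k1 = rep(2, 10), k2 = 10^runif(10)))
  expect_true(is.na(param_correlations(degen)$r["k1", "k2"]))
  expect_error(param_correlations(fake_archive(prob, rss = 1:2)), "3")
})

test_that("plot methods render to PNG and SVG files", {
  prob <- decay_problem()
  a <- fake_archive(prob, rss = c(1, 2, 3, 5, 8),
                    params = matrix(10^seq(-2, 2, 1), 5, 1,
                                    dimnames = list(NULL, "k")))
  dir <- withr::local_tempdir()
  paths <- render_figure(likelihood_ranks(a), file.path(dir, "lr"))
  paths <- c(paths, render_figure(param_distributions(a), file.path(dir, "pd")))
  paths <- c(paths, render_figure(
    ensemble_timecourse(a, top_k = 3, times = c(0, 1, 2), n_boot = 20),
    file.path(dir, "et")))
  cv <- profile_likelihood(decay_problem(), c(k = 0.1), "k",
                           span_orders = 1, n_points = 5)
  paths <- c(paths, render_figure(
    function() plot_profiles(list(list(k = cv))), file.path(dir, "pp")))
  rep <- select_models(list(m1 = a, m2 = a))
  paths <- c(paths, render_figure(function() plot_selection(rep),
                                  file.path(dir, "sel")))
  expect_true(all(file.exists(paths)))
  expect_true(all(file.size(paths) > 0))
  expect_setequal(tools::file_ext(paths), c("png", "svg"))
})
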