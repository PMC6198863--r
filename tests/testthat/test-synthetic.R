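test_that("motif fixtures parse, simulate, export and share observables", {
  mods <- motif_models()
  expect_named(mods, c("negative_feedback", "positive_feedback",
                       "feed_forward"))
  map <- motif_observation_map()
  for (m in mods) {
    tc <- simulate(m, times = c(0, 1, 4, 12))
    expect_true(all(is.finite(as.matrix(tc))))
    obs <- map_observation(tc, map)            # one map fits all three
    expect_equal(colnames(obs), c("X_obs", "Y_obs"))
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, path)
    expect_equal(read_sbml(path)$parameters, m$parameters)
  }

  # negative feedback overshoots then declines under the step input
  tt <- seq(0, 12, 0.25)
  x <- simulate(mods$negative_feedback, times = tt)$X
  expect_gt(max(x), 1.3 * x[length(x)])
  expect_lt(which.max(x), length(x) / 2)
  # positive feedback and feed-forward rise monotonically instead
  expect_false(is.unsorted(simulate(mods$positive_feedback, times = tt)$X))
  expect_false(is.unsorted(simulate(mods$feed_forward, times = tt)$X))

  # the committed .mdl fixtures match the in-code constructors
  for (nm in names(mods)) {
    path <- system.file("extdata", paste0(nm, ".mdl"), package = "odecal")
    expect_true(isTRUE(all.equal(parse_model(readLines(path)), mods[[nm]])))
  }
})

test_that("Smad7/Ski variants differ as designed", {
  sm <- smad_demo_models()
  # variants 1 and 2 differ only in one reaction's stoichiometry
  r1 <- sm$model_1$reactions[[5]]; r2 <- sm$model_2$reactions[[5]]
  expect_equal(r1$name, "Feedback")
  expect_equal(r1$rate_text, r2$rate_text)
  expect_equal(nrow(r1$reactants), 1)   # D only; Smad7 is a modifier
  expect_equal(nrow(r2$reactants), 2)   # D and Smad7 consumed
  expect_true("Smad7" %in% r1$modifiers)
  others_equal <- vapply(c(1:4), function(i)
    identical(sm$model_1$reactions[[i]]$rate_text,
              sm$model_2$reactions[[i]]$rate_text), TRUE)
  expect_true(all(others_equal))

  # variant 3: Ski decay flux is second order (doubling Ski quadruples it)
  ski_rate <- function(model, ski) {
    env <- as.list(model$parameters)
    env$Ski <- ski
    eval(model$reactions[[4]]$rate, env)
  }
  expect_equal(ski_rate(sm$model_3, 2) / ski_rate(sm$model_3, 1), 4)
  expect_equal(ski_rate(sm$model_2, 2) / ski_rate(sm$model_2, 1), 2)

  # Smad7 shows transient induction then decay under the step driver
  tt <- seq(0, 12, 0.25)
  s7 <- simulate(sm$model_2, times = tt)$Smad7
  expect_gt(max(s7), 2 * s7[length(s7)])
  expect_gt(which.max(s7), 1)
})

test_that("the data generator is seeded, noise-optional and lag-exact", {
  m <- smad_demo_models()$model_2
  map <- observation_map(c("Smad7_mRNA", "Ski_mRNA"), c("Smad7", "Ski"), 100)

  # noise "none": all replicates equal the mapped truth
  clean <- generate_data(m, noise = "none", map = map, seed = 1)
  truth <- map_observation(simulate(m, times = clean$times), map)
  for (r in seq_len(clean$n_replicates))
    expect_equal(clean$values[, r, ], unname(truth), tolerance = 1e-12,
                 ignore_attr = TRUE)

  # seeded determinism
  g1 <- generate_data(m, map = map, seed = 42)
  g2 <- generate_data(m, map = map, seed = 42)
  expect_identical(g1$values, g2$values)
  g3 <- generate_data(m, map = map, seed = 43)
  expect_false(identical(g1$values, g3$values))

  # protein rule: protein(t) = 100 * mRNA(t - 0.5 h), held at baseline early
  rule <- list(from = c(Smad7_protein = "Smad7_mRNA"), lag = 0.5,
               magnitude = 100, noisy = FALSE)
  withp <- generate_data(m, noise = "none", map = map, protein_rule = rule,
                         seed = 1)
  expect_true("Smad7_protein" %in% withp$observables)
  lagged <- map_observation(
    simulate(m, times = pmax(withp$times - 0.5, 0)), map)[, "Smad7_mRNA"]
  expect_equal(withp$values[, 1, "Smad7_protein"], 100 * lagged,
               tolerance = 1e-9)
  expect_equal(unname(withp$values[1, 1, "Smad7_protein"]),
               unname(100 * withp$values[1, 1, "Smad7_mRNA"]))

  # calibrating the generating model on its own noise-free data is exact
  prob <- fit_problem(m, clean, map, free = c("kV", "km", "I50"))
  expect_lt(weighted_rss(prob, c(kV = 2, km = 0.5, I50 = 0.3)), 1e-6)
})

test_that("inverse-synthesized qPCR plates normalize back to the table", {
  m <- smad_demo_models()$model_2
  map <- observation_map(c("Smad7_mRNA", "Ski_mRNA"), c("Smad7", "Ski"), 100)
  tab <- generate_data(m, noise = "lognormal", cv = 0.05, map = map, seed = 9)
  plate <- synthesize_qpcr(tab, ct_noise_sd = 0, rescale = TRUE, seed = 1)
  expect_s3_class(plate, "qpcr_plate")
  expect_equal(plate$reference_genes, c("B2M", "PPIA", "GAPDH", "ACTB"))
  rec <- ddct_normalize(plate)
  # reference: the table rescaled to baseline geometric mean 1
  v <- tab$values
  for (k in seq_along(tab$observables))
    v[, , k] <- v[, , k] / exp(mean(log(v[1, , k])))
  expect_lt(max(abs(rec$values[, , tab$observables] - v)), 1e-6)
  # zero expression cannot be synthesized
  tab$values[1, 1, 1] <- 0
  expect_error(synthesize_qpcr(tab), "positive")
})
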