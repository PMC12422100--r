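test_that("zero observations with no prior give zero extents", {
  S <- product_matrix("Rc&Mc&Mh&Dv")
  fit <- fit_extents(S, rep(0, nrow(S)))
  expect_equal(unname(fit$extents), rep(0, ncol(S)))
})

test_that("two-reaction fit matches the exhaustive grid-search oracle", {
  S <- product_matrix("Rc&Mc&Mh&Dv")[, c("acetoclastic_methanogenesis",
                                         "hydrogenotrophic_methanogenesis")]
  truth <- c(0.3, 0.1)
  y <- as.numeric(S %*% truth)
  fit <- fit_extents(S, y)
  expect_equal(unname(fit$extents), truth, tolerance = 1e-6)
  oracle <- grid_nnls(S, y, steps = 1e-3)  # exhaustive at 1e-3 over [0, 0.5]^2
  expect_equal(oracle$x, truth, tolerance = 2e-3)
  expect_lte(fit$objective, oracle$sse + 1e-12)
})

test_that("noise-free extents are recovered exactly on full-rank assemblies", {
  set.seed(42)
  for (label in FULL_RANK_ASSEMBLIES) {
    S <- product_matrix(label)
    for (trial in 1:5) {
      truth <- random_feasible_extents(label)[colnames(S)]
      y <- as.numeric(S %*% truth)
      fit <- fit_extents(S, y)
      expect_false(fit$rank_deficient)
      expect_lt(max(abs(fit$extents - truth) / pmax(truth, 1e-12)), 1e-6)
    }
  }
})

test_that("rank deficiency with Rc and Dv together is flagged, not fatal", {
  S <- product_matrix("Rc&Dv")
  truth <- c(0.5, 0.3, 0.2, 0.1)
  fit <- fit_extents(S, as.numeric(S %*% truth))
  expect_true(fit$rank_deficient)
  expect_match(fit$warning, "rank")
  # the fit still reproduces the observations even if extents are non-unique
  expect_equal(unname(fit$fitted), as.numeric(S %*% truth), tolerance = 1e-8)
})

test_that("increasing lambda moves extents monotonically toward the prior", {
  S <- product_matrix("Rc&Mc")
  truth <- c(0.5, 0.35, 0.29, 0.32)
  y <- as.numeric(S %*% truth) * 1.2  # inconsistent with the prior below
  prior <- stats::setNames(c(0.1, 0.1, 0.1, 0.1), colnames(S))
  dists <- vapply(c(0.001, 0.01, 0.1, 1, 10, 1e4), function(l) {
    f <- fit_extents(S, y, prior = prior, lambda = l)
    sqrt(sum((f$extents - prior)^2))
  }, numeric(1))
  expect_true(all(diff(dists) <= 1e-9))
  expect_lt(dists[length(dists)], 0.05)  # large lambda pins to the prior
  expect_error(fit_extents(S, y, lambda = 1), "prior")
})

test_that("trajectory mode recovers uniform daily extents from a clean series", {
  cfg <- generator_config("Rc&Mc", noise_cv = 0, replicates = 1,
                          seed = 3, catalogue = test_cat)
  sim <- simulate_culture(cfg)
  cum <- cumulative_production(sim$readings, test_cat, cfg$volumes)
  fit <- fit_culture(cum, "Rc&Mc", test_cat, mode = "trajectory")
  expect_equal(unname(fit$extent_mean[names(cfg$true_extents)]),
               unname(cfg$true_extents), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$nrmse, 0, tolerance = 1e-9)
})

test_that("goodness of fit matches hand-computed values", {
  perfect <- goodness_of_fit(c(0, 1, 2), c(0, 1, 2))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$nrmse, 0)
  g <- goodness_of_fit(c(0, 1, 2, 3), c(0.5, 1.5, 1.5, 2.5))
  expect_equal(g$r_squared, 0.8)
  expect_equal(g$nrmse, 0.5 / 3, tolerance = 1e-12)
  flat <- goodness_of_fit(c(2, 2, 2), c(2, 2.1, 1.9))
  expect_true(is.na(flat$r_squared))
  expect_match(flat$explanation, "zero variance")
})

test_that("proteomics priors follow the marker/ATP/rescaling rules", {
  ab <- matrix(c(0.4, 0.4, 0.1, 0.1, 0.02), ncol = 1,
               dimnames = list(c("p1", "p2", "p3", "p4", "bg"), "Rc&Mc"))
  mapping <- data.frame(
    protein = c("p1", "p2", "p3", "p4", "bg"),
    reaction = c("hydrogenic_acetogenesis", "hydrogenic_acetogenesis",
                 "acetoclastic_methanogenesis", "acetoclastic_methanogenesis",
                 NA))
  pr <- proteomics_prior(ab, mapping, test_cat, "Rc&Mc", atp_scaling = "none")
  # equal-abundance markers: prior ratio equals abundance ratio
  expect_equal(unname(pr$a["hydrogenic_acetogenesis"] /
                        pr$a["acetoclastic_methanogenesis"]), 4)
  expect_equal(sum(pr$a), 1)
  # ATP scaling multiplies the ratio by the ATP yields (4 vs 0.25)
  pr_atp <- proteomics_prior(ab, mapping, test_cat, "Rc&Mc")
  expect_equal(unname(pr_atp$a["hydrogenic_acetogenesis"] /
                        pr_atp$a["acetoclastic_methanogenesis"]),
               4 * 4 / 0.25)
  # reactions without markers get the mean prior of the covered ones
  covered <- c("hydrogenic_acetogenesis", "acetoclastic_methanogenesis")
  uncovered <- setdiff(names(pr$a), covered)
  expect_true(all(abs(pr$a[uncovered] - pr$a[uncovered][1]) < 1e-12))
  # global rescaling of abundances leaves the prior unchanged
  pr_scaled <- proteomics_prior(ab * 1000, mapping, test_cat, "Rc&Mc",
                                atp_scaling = "none")
  expect_equal(pr_scaled$a, pr$a)
  # all-zero abundances give an all-zero prior
  pr0 <- proteomics_prior(ab * 0, mapping, test_cat, "Rc&Mc")
  expect_equal(unname(pr0$a), rep(0, length(pr0$a)))
  expect_error(proteomics_prior(ab, mapping, test_cat, "Rc&Dv"), "not found")
})

test_that("replicate fits pool into mean, SD and range-normalized fit quality", {
  cfg <- generator_config("Rc&Mh", noise_cv = 0.05, replicates = 3,
                          seed = 11, catalogue = test_cat)
  sim <- simulate_culture(cfg)
  cum <- cumulative_production(sim$readings, test_cat, cfg$volumes)
  fit <- fit_culture(cum, "Rc&Mh", test_cat)
  expect_equal(nrow(fit$extents), 3)
  expect_true(all(fit$extents >= 0))
  expect_equal(unname(fit$extent_mean), unname(colMeans(fit$extents)))
  expect_gt(fit$r_squared, 0.9)
  expect_lt(fit$nrmse, 0.2)
})

test_that("bootstrap SD collapses for identical replicates and is seeded", {
  cfg <- generator_config("Rc&Mc", noise_cv = 0, replicates = 3,
                          seed = 5, catalogue = test_cat)
  sim <- simulate_culture(cfg)
  cum <- cumulative_production(sim$readings, test_cat, cfg$volumes)
  bs <- bootstrap_extents(cum, "Rc&Mc", test_cat, n_boot = 50, seed = 9)
  expect_equal(unname(bs$sd), rep(0, length(bs$sd)), tolerance = 1e-10)
  single <- fit_culture(cum[cum$replicate == 1, ], "Rc&Mc", test_cat)
  expect_equal(bs$mean, single$extent_mean, tolerance = 1e-8)
  bs2 <- bootstrap_extents(cum, "Rc&Mc", test_cat, n_boot = 50, seed = 9)
  expect_identical(bs$draws, bs2$draws)
  expect_error(bootstrap_extents(cum, "Rc&Mc", test_cat, n_boot = 1), "n_boot")
  expect_error(bootstrap_extents(cum[cum$replicate == 1, ], "Rc&Mc", test_cat,
                                 n_boot = 10), "replicates")
})

test_that("bootstrap SD tracks the noise level of the generator", {
  cfg <- generator_config("Rc&Mc", noise_cv = 0.05, replicates = 4,
                          seed = 21, catalogue = test_cat)
  sim <- simulate_culture(cfg)
  cum <- cumulative_production(sim$readings, test_cat, cfg$volumes)
  bs <- bootstrap_extents(cum, "Rc&Mc", test_cat, n_boot = 200, seed = 1)
  # Monte-Carlo truth: SD of replicate-mean extents across many fresh worlds
  mc <- vapply(1:40, function(s) {
    cfg_s <- generator_config("Rc&Mc", noise_cv = 0.05, replicates = 4,
                              seed = 1000 + s, catalogue = test_cat)
    sim_s <- simulate_culture(cfg_s)
    cum_s <- cumulative_production(sim_s$readings, test_cat, cfg_s$volumes)
    fit_culture(cum_s, "Rc&Mc", test_cat)$extent_mean
  }, numeric(4))
  mc_sd <- apply(mc, 1, stats::sd)
  big <- mc_sd > 1e-3  # compare on reactions with non-trivial spread
  expect_true(all(bs$sd[big] / mc_sd[big] > 0.3 & bs$sd[big] / mc_sd[big] < 3))
})
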