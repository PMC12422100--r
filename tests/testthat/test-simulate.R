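test_that("zero extents and zero noise give baseline readings everywhere", {
  cfg <- generator_config("Rc&Mc", true_extents = numeric(0), noise_cv = 0,
                          replicates = 1, seed = 1, catalogue = test_cat)
  sim <- simulate_culture(cfg)
  aq <- sim$readings[sim$readings$unit == "mM", ]
  expect_true(all(aq$value == 0))
  expect_true(all(sim$truth$mmol == 0))
  cum <- cumulative_production(sim$readings, test_cat, cfg$volumes)
  expect_equal(cum$mmol, rep(0, nrow(cum)), tolerance = 1e-12)
})

test_that("closed-form cumulative products match the stoichiometry", {
  cfg <- generator_config(
    "Rc&Mc", noise_cv = 0, replicates = 1, seed = 1,
    true_extents = c(hydrogenic_acetogenesis = 0.35,
                     acetoclastic_methanogenesis = 0.28),
    catalogue = test_cat)
  sim <- simulate_culture(cfg)
  final <- sim$truth[sim$truth$day == 7, ]
  expect_equal(final$mmol[final$analyte == "CH4"], 0.28)
  expect_equal(final$mmol[final$analyte == "acetate"], 2 * 0.35 - 0.28)
  expect_equal(final$mmol[final$analyte == "CO2"], 2 * 0.35 + 0.28)
  expect_equal(final$mmol[final$analyte == "H2"], 4 * 0.35)
})

test_that("generation is bitwise deterministic in the seed", {
  cfg <- generator_config("Rc&Mh&Dv", noise_cv = 0.05, seed = 123,
                          catalogue = test_cat)
  a <- simulate_culture(cfg)
  b <- simulate_culture(cfg)
  expect_identical(a$readings, b$readings)
  c <- simulate_culture(generator_config("Rc&Mh&Dv", noise_cv = 0.05,
                                         seed = 124, catalogue = test_cat))
  expect_false(identical(a$readings$value, c$readings$value))
  pa <- simulate_proteins(cfg)
  pb <- simulate_proteins(cfg)
  expect_identical(pa$abundance, pb$abundance)
})

test_that("noise-free generated series conserve carbon and electrons", {
  for (label in c("Rc&Mc", "Rc&Mc&Mh&Dv")) {
    cfg <- generator_config(label, noise_cv = 0, replicates = 1, seed = 1,
                            catalogue = test_cat)
    sim <- simulate_culture(cfg)
    final <- sim$truth[sim$truth$day == 7, ]
    mets <- test_cat$metabolites
    carbon <- mets$carbon[match(final$analyte, mets$id)]
    gamma <- mets$gamma[match(final$analyte, mets$id)]
    S_full <- build_matrix(active_reactions(label, test_cat), mets$id)
    glucose_used <- -sum((S_full %*% sim$true_extents[colnames(S_full)])["glucose", ])
    expect_equal(sum(final$mmol * carbon), 6 * glucose_used, tolerance = 1e-9)
    expect_equal(sum(final$mmol * gamma), 24 * glucose_used, tolerance = 1e-9)
  }
})

test_that("generator rejects inconsistent configurations", {
  expect_error(generator_config("Rc", true_extents =
                                  c(acetoclastic_methanogenesis = 0.1),
                                catalogue = test_cat), "inactive")
  expect_error(generator_config("Rc", true_extents =
                                  c(lactate_fermentation = -1),
                                catalogue = test_cat), "nonnegative")
  # consuming more H2 than is ever produced must fail loudly
  bad <- generator_config("Rc&Mh",
                          true_extents = c(hydrogenic_acetogenesis = 0.1,
                                           hydrogenotrophic_methanogenesis = 2),
                          noise_cv = 0, replicates = 1, seed = 1,
                          catalogue = test_cat)
  expect_error(simulate_culture(bad), "infeasible")
})

test_that("marker abundances track extents and normalize per species", {
  cfg <- generator_config(
    "Rc&Mc", protein_noise_cv = 0, seed = 6,
    true_extents = c(lactate_fermentation = 0.4,
                     hydrogenic_acetogenesis = 0.1,
                     acetoclastic_methanogenesis = 0.2),
    catalogue = test_cat)
  pr <- simulate_proteins(cfg)
  ab <- pr$abundance[, 1]
  # within a species the marker ratio equals the extent ratio (4:1)
  expect_equal(unname(ab["lactate_fermentation_marker1"] /
                        ab["hydrogenic_acetogenesis_marker1"]), 4)
  # per-species totals are normalized to 1
  for (sp in c("Rc", "Mc")) {
    idx <- pr$mapping$species == sp
    expect_equal(sum(ab[pr$mapping$protein[idx]]), 1)
  }
  # a zero-extent reaction's markers sit at background level
  cfg0 <- generator_config(
    "Rc&Mc", protein_noise_cv = 0, seed = 6,
    true_extents = c(lactate_fermentation = 0.4,
                     hydrogenic_acetogenesis = 0.1,
                     mixed_acid_fermentation = 0),
    catalogue = test_cat)
  pr0 <- simulate_proteins(cfg0)
  ab0 <- pr0$abundance[, 1]
  expect_equal(unname(ab0["mixed_acid_fermentation_marker1"]),
               unname(ab0["background_1"]))
})

test_that("noise-free round trips recover extents, R2 = 1 and NRMSE = 0", {
  for (label in FULL_RANK_ASSEMBLIES) {
    cfg <- generator_config(label, noise_cv = 0, replicates = 2, seed = 1,
                            catalogue = test_cat)
    rt <- round_trip_check(cfg)
    expect_lt(rt$max_rel_error, 1e-6)
    expect_lt(rt$max_abs_error_zero, 1e-9)
    expect_equal(rt$r_squared, 1, tolerance = 1e-9)
    expect_equal(rt$nrmse, 0, tolerance = 1e-9)
  }
})

test_that("the proteomics prior restores the identifiable directions with Dv", {
  cfg <- generator_config("Rc&Mc&Mh&Dv", noise_cv = 0, replicates = 1,
                          seed = 2, catalogue = test_cat)
  rt <- round_trip_check(cfg, use_prior = TRUE, lambda = 1e-4)
  # methanogenesis extents lie outside the null space and recover exactly
  expect_equal(unname(rt$extents["hydrogenotrophic_methanogenesis"]),
               unname(rt$true_extents[["hydrogenotrophic_methanogenesis"]]),
               tolerance = 1e-4)
  expect_equal(unname(rt$extents["acetoclastic_methanogenesis"]),
               unname(rt$true_extents[["acetoclastic_methanogenesis"]]),
               tolerance = 1e-4)
  expect_equal(rt$r_squared, 1, tolerance = 1e-6)
  # without the prior the same fit is flagged rank-deficient
  rt0 <- round_trip_check(cfg)
  expect_true(rt0$fit$rank_deficient)
})

test_that("recovery error grows with measurement noise in expectation", {
  err_at <- function(cv) {
    errs <- vapply(1:30, function(s) {
      cfg <- generator_config("Rc&Mc&Mh", noise_cv = cv, replicates = 1,
                              seed = 3000 + s, catalogue = test_cat)
      round_trip_check(cfg)$median_rel_error
    }, numeric(1))
    stats::median(errs)
  }
  expect_lte(err_at(0.02), err_at(0.10) + 1e-9)
})
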