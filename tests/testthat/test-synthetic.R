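test_that("ground truths are feasible, regime-consistent and seeded", {
  model <- buildNetwork("hypoxic")
  S <- stoichiometricMatrix(model)
  resp <- sampleGroundTruth(model, "respiratory", seed = 5)
  expect_lt(abs(resp[["adh_etoh"]]), 1e-9)
  expect_lt(abs(resp[["ara_ex"]]), 1e-9)
  expect_lt(max(abs(S %*% resp)), 1e-9)
  ferm <- sampleGroundTruth(model, "respiro_fermentative", seed = 5)
  expect_gt(ferm[["adh_etoh"]], 0.25 * 2.0 - 1e-9)
  expect_lt(max(abs(S %*% ferm)), 1e-9)
  # seeding: identical twice, distinct across seeds
  expect_identical(ferm,
                   sampleGroundTruth(model, "respiro_fermentative",
                                     seed = 5))
  expect_gt(max(abs(ferm - sampleGroundTruth(model, "respiro_fermentative",
                                             seed = 6))), 1e-6)
  # sampled ratios sit in the physiological acceptance band
  raw <- attr(suppressWarnings(computeRatios(ferm, model)), "raw")
  expect_true(all(raw[c("a", "c")] > 0.3 & raw[c("a", "c")] < 0.8))
  expect_true(raw[["d"]] > 0.1 && raw[["d"]] < 0.6)
})

test_that("noiseless simulation reproduces the truth exactly", {
  model <- buildNetwork("normoxic")
  truth <- sampleGroundTruth(model, "respiratory", seed = 2)
  ds <- simulateMeasurements(truth, model,
                             noise_spec = list(rate_rel = 0, rate_floor = 0,
                                               ratio_sd = c(a = 0, b = 0,
                                                            c = 0, d = 0)),
                             seed = 1)
  mids <- names(rateValues(ds@rates))
  expect_equal(rateValues(ds@rates), truth[mids])
  rs <- suppressWarnings(computeRatios(truth, model))
  expect_equal(ds@ratios@ratios, rs@ratios)
})

test_that("simulated datasets are reproducible and ratio noise is clipped", {
  model <- buildNetwork("hypoxic")
  truth <- sampleGroundTruth(model, "respiro_fermentative", seed = 3)
  d1 <- simulateMeasurements(truth, model, seed = 42)
  d2 <- simulateMeasurements(truth, model, seed = 42)
  expect_identical(rateValues(d1@rates), rateValues(d2@rates))
  expect_identical(d1@ratios@ratios, d2@ratios@ratios)
  # heavy noise never leaves [0, 1]
  big <- defaultNoiseSpec(); big$ratio_sd[] <- 0.5
  for (s in 1:25) {
    ds <- simulateMeasurements(truth, model, noise_spec = big, seed = s)
    vals <- ds@ratios@ratios[!is.na(ds@ratios@ratios)]
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("ratio noise has the stated Gaussian spread", {
  model <- buildNetwork("hypoxic")
  truth <- sampleGroundTruth(model, "respiro_fermentative", seed = 3)
  a_true <- suppressWarnings(computeRatios(truth, model))@ratios[["a"]]
  ns <- defaultNoiseSpec(); ns$ratio_sd <- c(a = 0.03, b = 0, c = 0, d = 0)
  hits <- vapply(1:1000, function(s)
    abs(simulateMeasurements(truth, model, noise_spec = ns,
                             seed = s)@ratios@ratios[["a"]] - a_true) <= 0.03,
    logical(1))
  # 68.3% +- binomial sampling error
  expect_gt(mean(hits), 0.63)
  expect_lt(mean(hits), 0.73)
})

test_that("recovery experiment: exact at zero noise, calibrated with noise", {
  model <- buildNetwork("hypoxic")
  zero <- list(rate_rel = 0, rate_floor = 0,
               ratio_sd = c(a = 0, b = 0, c = 0, d = 0))
  rec0 <- recoveryExperiment(model, "respiro_fermentative",
                             noise_spec = zero, n_reps = 1, seed = 4)
  expect_lt(max(abs(rec0$per_flux$bias) /
                pmax(abs(rec0$per_flux$truth), 1e-8)), 1e-6)
  rec <- recoveryExperiment(model, "respiro_fermentative",
                            n_reps = 60, seed = 4)
  expect_gt(sum(rec$per_flux$identifiable), 20)
  expect_gt(rec$coverage_identifiable, 0.85)
  # doubling the noise does not improve the error
  dbl <- defaultNoiseSpec()
  dbl$rate_rel <- dbl$rate_rel * 2; dbl$ratio_sd <- dbl$ratio_sd * 2
  rec2 <- recoveryExperiment(model, "respiro_fermentative",
                             noise_spec = dbl, n_reps = 60, seed = 4)
  id <- rec$per_flux$identifiable
  expect_gt(mean(rec2$per_flux$rmse[id]), 0.9 * mean(rec$per_flux$rmse[id]))
})

test_that("validation scenarios respect the pre-registered margin rule", {
  model <- buildNetwork("hypoxic")
  scen <- uncertaintyValidationScenario(model, seed = 1)
  expect_gte(scen$margin, 2)
  expect_length(scen$solution@active_bounds, 0)
  expect_false(scen$solution@inequality_active)
  # the inequality is absent by construction
  expect_length(scen$system@inequality, 0)
  expect_true(is.na(scen$system@ratios@ratios[["d"]]))
})
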