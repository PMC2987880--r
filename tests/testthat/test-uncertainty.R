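test_that("a single pinned rate propagates one-for-one along a chain", {
  sys <- toyChainSystem(q = 1)
  sol <- solveFluxes(sys)
  W <- sensitivityMatrix(sys, sol)
  expect_equal(dim(W), c(3L, 1L))
  expect_equal(unname(W[, 1]), c(1, 1, 1), tolerance = 1e-8)
})

test_that("analytic and finite-difference sensitivities agree", {
  model <- buildNetwork("hypoxic")
  truth <- sampleGroundTruth(model, "respiro_fermentative", seed = 9)
  ds <- simulateMeasurements(truth, model, seed = 10)
  sys <- assembleSystem(model, ds@rates, ds@ratios)
  sol <- solveFluxes(sys)
  Wa <- sensitivityMatrix(sys, sol, "analytic")
  Wf <- suppressWarnings(sensitivityMatrix(sys, sol, "finite_difference"))
  expect_lt(max(abs(Wa - Wf)), 1e-6)
  # strict mode too
  syss <- assembleSystem(model, ds@rates, ds@ratios, strict = TRUE)
  sols <- solveFluxes(syss)
  Was <- sensitivityMatrix(syss, sols, "analytic")
  Wfs <- suppressWarnings(sensitivityMatrix(syss, sols,
                                            "finite_difference"))
  expect_lt(max(abs(Was - Wfs)), 1e-6)
})

test_that("a parameter no flux depends on gives a zero column", {
  # two disconnected coordinates, each with its own measurement
  N <- diag(2); colnames(N) <- c("v1", "v2")
  sys <- bareSystem(N, b = c(1, 2), sds = c(0.1, 0.1))
  sol <- solveFluxes(sys)
  W <- sensitivityMatrix(sys, sol)
  expect_equal(unname(W), diag(2), tolerance = 1e-8)
  expect_equal(W["v1", "rate:m2"], 0, tolerance = 1e-10)
})

test_that("fisherInformation implements W^T C^-1 W with block sums", {
  expect_equal(fisherInformation(diag(3), diag(3)), diag(3))
  expect_equal(fluxSd(fisherInformation(diag(3), diag(3))),
               rep(1, 3), ignore_attr = TRUE)
  # quadrupling C doubles every sigma
  W <- matrix(rnorm(12), 4, 3)
  C <- diag(runif(4, 0.5, 2))
  s1 <- fluxSd(fisherInformation(W, C))
  s2 <- fluxSd(fisherInformation(W, 4 * C))
  expect_equal(s2, 2 * s1, tolerance = 1e-10)
  # block sum equals stacked computation
  W2 <- matrix(rnorm(6), 2, 3)
  C2 <- diag(c(1, 2))
  FIMb <- fisherInformation(list(W, W2), list(C, C2))
  FIMs <- fisherInformation(rbind(W, W2),
                            diag(c(diag(C), diag(C2))))
  expect_equal(FIMb, FIMs, tolerance = 1e-12)
  expect_error(fisherInformation(W, diag(3)), "conform")
  expect_error(fisherInformation(W, 0 * C), "positive definite")
  expect_warning(fluxSd(matrix(0, 2, 2)), "singular")
})

test_that("FIM sigma equals the analytic covariance when unconstrained", {
  sys <- randomBareSystem(p = 5, n = 9, seed = 3)
  sol <- solveFluxes(sys)
  oracle <- wlsOracle(sys@N, sys@b, sys@row_sd)
  # route 1: estimator-sensitivity covariance (the pipeline)
  unc <- fluxUncertainty(sys, sol)
  expect_lt(max(abs(unc@sigma - sqrt(diag(oracle$cov)))), 1e-8)
  # route 2: the paper-form FIM from the measurement model
  FIM <- fisherInformation(sys@N, diag(sys@row_sd^2))
  expect_lt(max(abs(fluxSd(FIM) - sqrt(diag(oracle$cov)))), 1e-8)
  # FIM symmetric positive semidefinite
  ev <- eigen(unc@FIM, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_equal(unc@FIM, t(unc@FIM))
})

test_that("interval widths grow with measurement variance", {
  sys <- randomBareSystem(p = 4, n = 7, seed = 5)
  sol <- solveFluxes(sys)
  s1 <- fluxUncertainty(sys, sol)@sigma
  sys2 <- sys
  sys2@row_sd[3] <- sys2@row_sd[3] * 3   # inflate one measurement sd
  s2 <- fluxUncertainty(sys2, solveFluxes(sys2))@sigma
  expect_true(all(s2 >= s1 - 1e-12))
})

test_that("confidence intervals follow the Student-t quantile", {
  est <- c(f1 = 2, f2 = -1)
  sig <- c(f1 = 0.5, f2 = 0)
  ci <- confidenceIntervals(est, sig, alpha = 0.05, v = Inf)
  expect_equal(ci$ci_high - ci$ci_low,
               2 * qnorm(0.975) * unname(sig), tolerance = 1e-12)
  expect_equal(ci$ci_low[2], ci$ci_high[2])   # zero sigma, zero width
  expect_equal(ci$ci_high[1] - ci$estimate[1], 1.959964 * 0.5,
               tolerance = 1e-6)
  # alpha = 0.32 at large dof: half-width is about one sigma
  ci32 <- confidenceIntervals(est, sig, alpha = 0.32, v = 1e6)
  expect_equal(ci32$ci_high[1] - ci32$estimate[1], 0.5, tolerance = 1e-2)
  # finite dof widens the interval
  ci5 <- confidenceIntervals(est, sig, alpha = 0.05, v = 5)
  expect_gt(ci5$ci_high[1], ci$ci_high[1])
  expect_error(confidenceIntervals(est, sig, alpha = 1.2), "alpha")
  expect_error(confidenceIntervals(est, sig, v = 0.5), "v must be")
})

test_that("Monte-Carlo resampling reproduces the FIM sigma when the
           linearization premise holds", {
  model <- buildNetwork("hypoxic")
  scen <- uncertaintyValidationScenario(model, seed = 21)
  expect_gte(scen$margin, 2)
  mc <- monteCarloCheck(scen$system, n_reps = 200, seed = 22)
  relsd <- scen$uncertainty@sigma / pmax(abs(scen$solution@x), 1e-3)
  ident <- relsd <= 0.5 & scen$uncertainty@flags == ""
  idx <- mc$flux_id %in% names(which(ident))
  expect_gte(sum(idx), 20)
  expect_true(all(mc$ratio[idx] > 0.8 & mc$ratio[idx] < 1.2))
  # determinism: identical seed, identical table
  mc2 <- monteCarloCheck(scen$system, n_reps = 50, seed = 7)
  mc3 <- monteCarloCheck(scen$system, n_reps = 50, seed = 7)
  expect_identical(mc2, mc3)
})

test_that("near-zero measurement noise yields near-zero empirical sd", {
  sys <- toyChainSystem(q = 1, sd = 1e-8)
  mc <- monteCarloCheck(sys, n_reps = 20, seed = 1)
  expect_lt(max(mc$empirical_sd), 1e-6)
})
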