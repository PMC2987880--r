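test_that("a pinned linear chain carries the measured flux everywhere", {
  sys <- toyChainSystem(q = 1)
  sol <- solveFluxes(sys)
  expect_equal(unname(sol@x), c(1, 1, 1), tolerance = 1e-10)
  expect_lt(max(abs(sol@residuals)), 1e-10)
  expect_equal(sol@weighted_ssr, 0, tolerance = 1e-12)
  expect_lt(sol@kkt_residual, 1e-10)
  expect_length(sol@active_bounds, 0)
})

test_that("system assembly checks inputs and annotates rows", {
  model <- buildNetwork("hypoxic")
  rates <- rateTable(c(glc_upt = 2))
  expect_error(assembleSystem(model, rateTable(c(nope = 1)),
                              emptyRatioSet("hypoxic")), "unknown")
  expect_error(assembleSystem(model, rates, emptyRatioSet("normoxic")),
               "condition")
  sys <- hypoxicFixtureSystem()
  expect_equal(ncol(sys@N), 34L)
  expect_equal(sum(sys@row_type == "balance"), 15L)
  expect_equal(sum(sys@row_type == "ratio"), 2L)      # a and c
  expect_length(sys@inequality, 34L)                  # d bound present
  expect_true(all(sys@b[sys@row_type == "ratio"] == 0))
  # empty ratio set still assembles, with no ratio rows
  sys0 <- assembleSystem(model, rateTable(c(glc_upt = 2)),
                         emptyRatioSet("hypoxic"))
  expect_equal(sum(sys0@row_type == "ratio"), 0L)
  expect_length(sys0@inequality, 0L)
})

test_that("whitened and unweighted modes share the row span", {
  model <- buildNetwork("hypoxic")
  state <- packagedChemostat("hypoxic")
  rates <- combineRates(specificRates(state), drainRates(0.1))
  ratios <- packagedRatios("expressing", "hypoxic")
  w <- assembleSystem(model, rates, ratios, weighting = "whitened")
  u <- assembleSystem(model, rates, ratios, weighting = "unweighted")
  expect_equal(u@weights, rep(1, nrow(u@N)))
  expect_false(isTRUE(all.equal(w@weights, u@weights)))
  # same rows, different scaling only
  expect_equal(w@N, u@N)
})

test_that("solver matches the closed-form weighted normal equations", {
  sys <- randomBareSystem(p = 5, n = 9, seed = 2)
  sol <- solveFluxes(sys)
  oracle <- wlsOracle(sys@N, sys@b, sys@row_sd)
  expect_lt(max(abs(sol@x - oracle$x)), 1e-8)
  expect_length(sol@active_bounds, 0)
  expect_equal(sol@dof, 4L)  # 9 rows - 5 free parameters
})

test_that("solver agrees with a brute-force grid on a tiny network", {
  # A_ext -> A, A -> B -> B_ext, A -> C -> C_ext; 2 free dimensions
  mets <- data.frame(
    id = c("A_ext", "A", "B", "C", "B_ext", "C_ext"),
    name = c("Ae", "A", "B", "C", "Be", "Ce"),
    compartment = c("external", rep("cytosol", 3), "external", "external"),
    balanced = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    carbon_count = 1L, stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("upt", "r1", "r2", "excB", "excC"),
    name = c("upt", "r1", "r2", "excB", "excC"),
    reversible = FALSE,
    category = c("exchange", "glycolysis", "ppp", "exchange", "exchange"),
    ratio_alias = NA_character_,
    stoich = I(list(c(A_ext = -1, A = 1), c(A = -1, B = 1),
                    c(A = -1, C = 1), c(B = -1, B_ext = 1),
                    c(C = -1, C_ext = 1))),
    stringsAsFactors = FALSE)
  model <- new("NetworkModel", metabolites = mets, reactions = rxns,
               condition = "normoxic")
  rates <- rateTable(c(upt = 1, excB = 0.72, excC = 0.21),
                     sds = c(upt = 0.05, excB = 0.05, excC = 0.1))
  sys <- assembleSystem(model, rates, emptyRatioSet("normoxic"))
  # inject an inequality r1 - 2 r2 <= 0 that cuts off the unconstrained
  # optimum (0.72 - 0.42 > 0)
  ineq <- stats::setNames(c(0, 1, -2, 0, 0), reactionIds(model))
  sys@inequality <- ineq
  sys@inequality_rhs <- 0
  sol <- solveFluxes(sys)
  # brute force: balances give x = (r1+r2, r1, r2, r1, r2)
  w <- 1 / rateSds(rates)
  obj <- function(r1, r2)
    (w[["upt"]] * (r1 + r2 - 1))^2 + (w[["excB"]] * (r1 - 0.72))^2 +
    (w[["excC"]] * (r2 - 0.21))^2
  grid <- expand.grid(r1 = seq(0, 1.5, by = 0.002),
                      r2 = seq(0, 1.5, by = 0.002))
  grid <- grid[grid$r1 - 2 * grid$r2 <= 0, ]
  vals <- obj(grid$r1, grid$r2)
  best <- grid[which.min(vals), ]
  expect_true(sol@inequality_active)
  expect_lt(abs(sol@x[["r1"]] - best$r1), 0.004)
  expect_lt(abs(sol@x[["r2"]] - best$r2), 0.004)
  # the solver is never worse than the best grid point
  expect_lte(obj(sol@x[["r1"]], sol@x[["r2"]]), min(vals) + 1e-10)
})

test_that("noiseless synthetic measurements are recovered exactly", {
  model <- buildNetwork("hypoxic")
  truth <- sampleGroundTruth(model, "respiro_fermentative", seed = 8)
  ds <- simulateMeasurements(truth, model,
                             noise_spec = list(rate_rel = 0, rate_floor = 0,
                                               ratio_sd = c(a = 0, b = 0,
                                                            c = 0, d = 0)),
                             seed = 8)
  sol <- solveFluxes(assembleSystem(model, ds@rates, ds@ratios))
  expect_lt(max(abs(sol@x - truth) / pmax(abs(truth), 1e-8)), 1e-6)
  # balance residuals vanish when measurements are consistent
  bal <- sol@residuals[sol@system@row_type == "balance"]
  expect_lt(max(abs(bal)), 1e-9)
})

test_that("solution is invariant under joint rescaling of measurements", {
  # scaling every soft (measurement-derived) row and its rhs by a common
  # factor leaves the estimate unchanged
  sys <- hypoxicFixtureSystem()
  sol <- solveFluxes(sys)
  sys2 <- sys
  mi <- sys2@row_type != "balance"
  sys2@N[mi, ] <- 3 * sys2@N[mi, ]
  sys2@b[mi] <- 3 * sys2@b[mi]
  sol2 <- solveFluxes(sys2)
  expect_equal(sol2@x, sol@x, tolerance = 1e-8)
})

test_that("structurally free directions raise a named error", {
  model <- buildNetwork("hypoxic")
  state <- packagedChemostat("hypoxic")
  rates <- combineRates(specificRates(state), drainRates(0.1))
  # dropping the ratio constraints leaves the Oaa transport cycle free
  sys <- assembleSystem(model, rates, emptyRatioSet("hypoxic"))
  expect_error(solveFluxes(sys), "underdetermined.*oaa")
  expect_warning(sol <- solveFluxes(sys, on_underdetermined = "min-norm"),
                 "minimum-norm")
  expect_true(is.finite(sol@weighted_ssr))
})

test_that("strict mode pins the measurements exactly", {
  model <- buildNetwork("hypoxic")
  state <- packagedChemostat("hypoxic")
  rates <- combineRates(specificRates(state), drainRates(0.1))
  ratios <- packagedRatios("expressing", "hypoxic")
  soft <- solveFluxes(assembleSystem(model, rates, ratios))
  # soft mode compromises the glucose measurement on this fixture
  expect_gt(abs(soft@x[["glc_upt"]] - rateValues(rates)[["glc_upt"]]),
            1e-3)
  strict <- solveFluxes(assembleSystem(model, rates, ratios,
                                       strict = TRUE))
  mi <- strict@system@row_type == "measurement"
  expect_lt(max(abs(strict@residuals[mi])), 1e-8)
})

test_that("branch fractions report the three node splits", {
  model <- buildNetwork("hypoxic")
  x <- stats::setNames(rep(0, 34), reactionIds(model))
  x[c("pdh", "pdc", "pyc")] <- c(6, 3, 1)
  x["glc_upt"] <- 10; x["zwf"] <- 0; x["pgi"] <- 10
  x["tca_mdh"] <- 4; x["oaa_in"] <- 2; x["oaa_out"] <- 1
  bf <- branchFractions(x, model)
  expect_equal(bf$pyruvate, list(pdh = 0.6, pdc = 0.3, pyc = 0.1))
  expect_equal(bf$g6p, list(ppp = 0, glycolysis = 1))
  expect_equal(bf$tca$respirative, 4 / 5)
  expect_true(bf$tca$respirative >= 0 && bf$tca$respirative <= 1)
  # zero node throughput flagged
  x0 <- stats::setNames(rep(0, 34), reactionIds(model))
  expect_warning(branchFractions(x0, model), "zero")
})

test_that("normalization maps glucose uptake to one and is scale-free", {
  sys <- hypoxicFixtureSystem()
  sol <- solveFluxes(sys)
  n1 <- normalizeFluxes(sol)
  expect_equal(unname(n1[["glc_upt"]]), 1)
  expect_equal(normalizeFluxes(2 * sol@x), n1, tolerance = 1e-12)
  bad <- sol@x; bad["glc_upt"] <- 0
  expect_error(normalizeFluxes(bad), "zero")
})
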