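test_that("ratios evaluate the documented formulas at alias fluxes", {
  hyp <- buildNetwork("hypoxic")
  x <- aliasFluxVector(hyp, x23 = 11, x16 = 9, x17 = 2, x24 = 1,
                       x3 = 10, x9 = 2, x10 = 1, x11 = 1)
  rs <- computeRatios(x, hyp)
  expect_equal(unname(rs@ratios[["a"]]), 11 / 20)
  expect_equal(unname(rs@ratios[["c"]]), 2 / 3)
  expect_equal(unname(rs@ratios[["d"]]), (2 + 2 + 3) / (20 + 2 + 1))
  # boundary: no transport into the mitochondria
  x0 <- aliasFluxVector(hyp, x23 = 0, x16 = 9, x17 = 2, x24 = 1,
                        x3 = 10, x9 = 2, x10 = 1, x11 = 1)
  expect_equal(unname(computeRatios(x0, hyp)@ratios[["a"]]), 0)
})

test_that("out-of-range raw ratios are reported with a warning", {
  hyp <- buildNetwork("hypoxic")
  x <- aliasFluxVector(hyp, x23 = 1, x16 = 1, x17 = 1, x24 = 1,
                       x3 = 1, x9 = 1, x10 = 1, x11 = 1)
  expect_warning(rs <- computeRatios(x, hyp), "outside \\[0, 1\\]")
  expect_equal(unname(attr(rs, "raw")[["d"]]), 1.5)
  expect_equal(unname(rs@ratios[["d"]]), 1)  # clipped in the valid object
})

test_that("zero denominators raise named errors", {
  hyp <- buildNetwork("hypoxic")
  x <- aliasFluxVector(hyp, x23 = 0, x16 = 0, x17 = 1, x24 = 1,
                       x3 = 1, x9 = 1, x10 = 1, x11 = 1)
  expect_error(computeRatios(x, hyp), "ratio 'a'")
})

test_that("constraint rows place the substituted coefficients at aliases", {
  hyp <- buildNetwork("hypoxic")
  am <- aliasMap(hyp)
  rs <- RatioSet("hypoxic", a = 0.5, sd_a = 0.03, c = 0.25, sd_c = 0.04,
                 d = 0.2, sd_d = 0.07)
  cr <- assembleConstraintRows(rs, hyp)
  expect_equal(nrow(cr$equality_matrix), 2L)
  arow <- cr$equality_matrix["a", ]
  expect_equal(unname(arow[am[["x23"]]]), 0.5)
  expect_equal(unname(arow[am[["x16"]]]), -0.5)
  expect_equal(sum(arow != 0), 2L)
  crow <- cr$equality_matrix["c", ]
  expect_equal(unname(crow[am[["x17"]]]), 0.75)
  expect_equal(unname(crow[am[["x24"]]]), -0.25)
  expect_equal(cr$equality_rhs, c(0, 0))
  expect_equal(cr$row_weights, c(1 / 0.03, 1 / 0.04))
  ineq <- cr$inequality_row
  expect_equal(unname(ineq[am[["x9"]]]), 0.8)
  expect_equal(unname(ineq[am[["x11"]]]), 2)
  expect_equal(unname(ineq[am[["x10"]]]), 2.8)
  expect_equal(unname(ineq[am[["x3"]]]), -2)
  expect_equal(sum(ineq != 0), 4L)
})

test_that("a = 0 reduces the row to pinning the transport flux", {
  hyp <- buildNetwork("hypoxic")
  rs <- RatioSet("hypoxic", a = 0, sd_a = 0.03)
  cr <- assembleConstraintRows(rs, hyp)
  arow <- cr$equality_matrix["a", ]
  expect_equal(unname(arow[aliasMap(hyp)[["x23"]]]), 1)
  expect_equal(sum(arow != 0), 1L)
})

test_that("normoxic sets use the net-transport row and forbid a/c", {
  nor <- buildNetwork("normoxic")
  rs <- RatioSet("normoxic", b = 0.43, sd_b = 0.03)
  cr <- assembleConstraintRows(rs, nor)
  brow <- cr$equality_matrix["b", ]
  am <- aliasMap(nor)
  expect_equal(unname(brow[am[["x23star"]]]), 0.57)
  expect_equal(unname(brow[am[["x16"]]]), -0.43)
  expect_null(cr$inequality_row)
  expect_error(RatioSet("normoxic", a = 0.5, sd_a = 0.03),
               "not determinable")
  expect_error(RatioSet("hypoxic", b = 0.5, sd_b = 0.03), "normoxic")
  # condition mismatch between set and model
  expect_error(assembleConstraintRows(rs, buildNetwork("hypoxic")),
               "condition")
})

test_that("equality rows annihilate the flux vector they came from", {
  # the defining property: rows built from computeRatios(x) satisfy
  # row . x = 0 to machine precision, and ratios are scale-invariant
  hyp <- buildNetwork("hypoxic")
  nor <- buildNetwork("normoxic")
  set.seed(11)
  for (i in 1:250) {
    model <- if (i %% 2) hyp else nor
    vals <- runif(8, 0.05, 5)
    x <- if (i %% 2)
      aliasFluxVector(model, x23 = vals[1], x16 = vals[2], x17 = vals[3],
                      x24 = vals[4], x3 = vals[5], x9 = vals[6],
                      x10 = vals[7], x11 = vals[8])
    else
      aliasFluxVector(model, x23star = vals[1], x16 = vals[2],
                      x17 = vals[3], x3 = vals[5], x9 = vals[6],
                      x10 = vals[7], x11 = vals[8])
    rs <- suppressWarnings(computeRatios(x, model))
    rs@sds[!is.na(rs@ratios)] <- 0.05
    cr <- assembleConstraintRows(rs, model)
    prods <- as.numeric(cr$equality_matrix %*% x)
    expect_lt(max(abs(prods)), 1e-12 * max(abs(vals)))
    sc <- suppressWarnings(computeRatios(7.3 * x, model))
    expect_equal(sc@ratios, rs@ratios, tolerance = 1e-12)
  }
})

test_that("packaged ratio measurements match the published values", {
  rs <- packagedRatios("expressing", "normoxic")
  expect_equal(unname(rs@ratios[["d"]]), 0.50)
  expect_equal(unname(rs@sds[["d"]]), 0.09)
  expect_equal(unname(rs@ratios[["b"]]), 0.44)
  expect_true(is.na(rs@ratios[["a"]]))
  rs <- packagedRatios("expressing", "hypoxic")
  expect_equal(unname(rs@ratios[["a"]]), 0.55)
  expect_equal(unname(rs@sds[["a"]]), 0.03)
  rs <- packagedRatios("control", "oxygen_limited")
  expect_equal(unname(rs@ratios[["c"]]), 0.66)
  expect_equal(unname(rs@sds[["c"]]), 0.03)
  # diagnostic rows ride along as annotations only
  expect_true("oaa_cyt_fum_reversible" %in% rs@annotations$ratio)
})
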