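test_that("condition variants carry the documented reaction counts", {
  expect_equal(nReactions(buildNetwork("normoxic")), 33L)
  expect_equal(nReactions(buildNetwork("oxygen_limited")), 34L)
  expect_equal(nReactions(buildNetwork("hypoxic")), 34L)
  expect_error(buildNetwork("anaerobic"))
})

test_that("normoxia replaces the Oaa transport pair by one net reaction", {
  nor <- buildNetwork("normoxic")
  hyp <- buildNetwork("hypoxic")
  expect_setequal(setdiff(reactionIds(hyp), reactionIds(nor)),
                  c("oaa_in", "oaa_out"))
  expect_setequal(setdiff(reactionIds(nor), reactionIds(hyp)), "oaa_net")
  expect_true(reactions(nor)$reversible[reactions(nor)$id == "oaa_net"])
  expect_equal(unname(aliasMap(nor)[["x23star"]]), "oaa_net")
  # acetyl-CoA crosses no membrane in any variant
  for (m in list(nor, hyp)) {
    tr <- reactions(m)[reactions(m)$category == "transport", ]
    expect_false(any(grepl("AcCoA", unlist(lapply(tr$stoich, names)))))
  }
})

test_that("stoichiometric matrix has balanced-metabolite rows only", {
  S <- stoichiometricMatrix(toyChainModel())
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(S["A", ], c(upt = 1, conv = -1, exc = 0))
  expect_equal(S["B", ], c(upt = 0, conv = 1, exc = -1))
  expect_equal(ncol(stoichiometricMatrix(buildNetwork("hypoxic"))), 34L)
  # a reaction touching no balanced species is flagged
  bad <- toyChainModel()
  bad@reactions$stoich[[3]] <- c(B_ext = 1)
  expect_error(stoichiometricMatrix(bad), "all-zero")
})

test_that("validateNetwork reports aliases, orphans and carbon balance", {
  for (cond in c("normoxic", "oxygen_limited", "hypoxic")) {
    v <- validateNetwork(buildNetwork(cond))
    expect_length(v$missing_aliases, 0)
    expect_length(v$orphans, 0)
    expect_length(v$carbon_imbalance, 0)
    expect_true(v$ok)
  }
  orphaned <- toyChainModel()
  orphaned@metabolites <- rbind(
    orphaned@metabolites,
    data.frame(id = "C", name = "C", compartment = "cytosol",
               balanced = TRUE, carbon_count = 1L))
  orphaned@reactions$stoich[[2]] <- c(A = -1, B = 1, C = 0.1)
  v <- validateNetwork(orphaned)
  expect_true("C" %in% v$orphans)
})

test_that("model validity catches structural mistakes", {
  m <- toyChainModel()
  m@reactions$id[2] <- "upt"
  expect_error(validObject(m), "duplicate")
  m <- toyChainModel()
  m@metabolites$balanced[1] <- TRUE  # external cannot be balanced
  expect_error(validObject(m), "external")
})

test_that("every variant admits a strictly feasible steady-state flux", {
  for (cond in c("normoxic", "oxygen_limited", "hypoxic")) {
    model <- buildNetwork(cond)
    x <- sampleGroundTruth(model, "respiro_fermentative", seed = 3)
    S <- stoichiometricMatrix(model)
    expect_lt(max(abs(S %*% x)), 1e-9)
    irr <- !reactions(model)$reversible
    expect_true(all(x[irr] >= -1e-12))
  }
})

test_that("JSON round-trip is the identity on packaged models", {
  path <- tempfile(fileext = ".json")
  for (cond in c("normoxic", "hypoxic")) {
    m <- buildNetwork(cond)
    writeNetwork(m, path)
    m2 <- readNetwork(path)
    expect_equal(m2@condition, m@condition)
    expect_equal(m2@metabolites, m@metabolites)
    expect_equal(m2@reactions$id, m@reactions$id)
    expect_equal(m2@reactions$ratio_alias, m@reactions$ratio_alias)
    for (i in seq_len(nReactions(m)))
      expect_equal(m2@reactions$stoich[[i]], m@reactions$stoich[[i]])
  }
})

test_that("JSON parsing errors name the offending entity", {
  path <- tempfile(fileext = ".json")
  m <- buildNetwork("normoxic")
  writeNetwork(m, path)
  txt <- readLines(path)
  dup <- sub('"pgi"', '"glc_upt"', txt)  # duplicate reaction id
  writeLines(dup, path)
  expect_error(readNetwork(path), "duplicate reaction id")
})

test_that("exact rational coefficients survive the round-trip", {
  path <- tempfile(fileext = ".json")
  m <- toyChainModel()
  writeNetwork(m, path)
  obj <- jsonlite::read_json(path)
  obj$reactions[[2]]$stoich$B <- "1/3"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  m2 <- readNetwork(path)
  expect_equal(unname(m2@reactions$stoich[[2]][["B"]]), 1 / 3)
  path2 <- tempfile(fileext = ".json")
  writeNetwork(m2, path2)
  expect_true(any(grepl('"1/3"', readLines(path2))))
})

test_that("alias overrides remap and revalidate", {
  m <- buildNetwork("hypoxic")
  m2 <- setAliases(m, c(x3 = "pyk"))
  expect_equal(unname(aliasMap(m2)[["x3"]]), "pyk")
  expect_error(setAliases(m, c(x3 = "nope")), "unknown reaction")
  expect_error(setAliases(m, c(zz = "pyk")), "unknown ratio alias")
})
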