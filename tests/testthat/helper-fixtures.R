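# Shared builders for small test networks and systems.

# linear chain A_ext -> A -> B -> B_ext with A, B balanced
toyChainModel <- function() {
  mets <- data.frame(
    id = c("A_ext", "A", "B", "B_ext"),
    name = c("A (medium)", "A", "B", "B (excreted)"),
    compartment = c("external", "cytosol", "cytosol", "external"),
    balanced = c(FALSE, TRUE, TRUE, FALSE),
    carbon_count = c(1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("upt", "conv", "exc"),
    name = c("uptake", "conversion", "excretion"),
    reversible = c(FALSE, FALSE, FALSE),
    category = c("exchange", "glycolysis", "exchange"),
    ratio_alias = NA_character_,
    stoich = I(list(c(A_ext = -1, A = 1),
                    c(A = -1, B = 1),
                    c(B = -1, B_ext = 1))),
    stringsAsFactors = FALSE)
  new("NetworkModel", metabolites = mets, reactions = rxns,
      condition = "normoxic")
}

toyChainSystem <- function(q = 1, sd = 0.05) {
  model <- toyChainModel()
  rates <- rateTable(c(upt = q), sds = c(upt = sd))
  assembleSystem(model, rates, emptyRatioSet("normoxic"))
}

# a flux vector over a model with given alias fluxes, zero elsewhere
aliasFluxVector <- function(model, ...) {
  vals <- c(...)
  x <- stats::setNames(rep(0, nReactions(model)), reactionIds(model))
  am <- aliasMap(model)
  for (nm in names(vals)) {
    id <- if (nm %in% names(am)) am[[nm]] else nm
    x[[id]] <- vals[[nm]]
  }
  x
}

# random full-rank unconstrained least-squares system (all measurement rows)
randomBareSystem <- function(p = 5, n = 9, seed = 1) {
  set.seed(seed)
  N <- matrix(rnorm(n * p), n, p)
  colnames(N) <- paste0("v", seq_len(p))
  b <- rnorm(n)
  sds <- runif(n, 0.2, 2)
  bareSystem(N, b, sds = sds)
}

# closed-form weighted least-squares estimate and covariance
wlsOracle <- function(N, b, sds) {
  Cinv <- diag(1 / sds^2)
  H <- t(N) %*% Cinv %*% N
  xhat <- solve(H, t(N) %*% Cinv %*% b)
  list(x = as.numeric(xhat), cov = solve(H))
}

hypoxicFixtureSystem <- function(strain = "expressing") {
  model <- buildNetwork("hypoxic")
  state <- packagedChemostat("hypoxic")
  rates <- combineRates(specificRates(state),
                        drainRates(state$dilution_rate))
  assembleSystem(model, rates, packagedRatios(strain, "hypoxic"))
}
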