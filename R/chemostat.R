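#' Molar masses of the measured species
#'
#' @return named numeric vector, g/mol.
#' @export
defaultMolarMasses <- function() {
  c(glucose = 180.156, ethanol = 46.069, glycerol = 92.094,
    arabitol = 152.146)
}

#' Construct a chemostat steady-state record
#'
#' @param dilution_rate dilution rate D (1/h); at steady state the specific
#'   growth rate equals D.
#' @param feed_glucose glucose concentration in the feed (g/L).
#' @param residual_glucose residual glucose in the broth (g/L); 0 under
#'   carbon limitation (below detection).
#' @param biomass dry biomass concentration X (gDCW/L).
#' @param products named numeric vector of broth product concentrations
#'   (g/L), e.g. `c(ethanol = 6.85, arabitol = 2.88)`.
#' @param OUR,CER oxygen uptake and carbon evolution rates
#'   (mmol gDCW^-1 h^-1); diagnostics only, never balanced in the model.
#' @param sds optional named list of standard deviations for any of the
#'   above fields.
#' @return an object of class `ChemostatState` (validated list).
#' @export
chemostatState <- function(dilution_rate, feed_glucose, residual_glucose = 0,
                           biomass, products = numeric(), OUR = NA_real_,
                           CER = NA_real_, sds = list()) {
  stopifnot(dilution_rate > 0, biomass > 0, feed_glucose >= 0,
            residual_glucose >= 0)
  if (length(products) && (is.null(names(products)) || any(products < 0)))
    stop("products must be a named non-negative vector")
  structure(list(dilution_rate = dilution_rate, feed_glucose = feed_glucose,
                 residual_glucose = residual_glucose, biomass = biomass,
                 products = products, OUR = OUR, CER = CER, sds = sds),
            class = "ChemostatState")
}

#' @export
print.ChemostatState <- function(x, ...) {
  cat(sprintf("ChemostatState: D = %.3g 1/h, X = %.4g gDCW/L, feed = %.4g g/L\n",
              x$dilution_rate, x$biomass, x$feed_glucose))
  if (length(x$products))
    cat("  products (g/L):",
        paste(sprintf("%s = %.3g", names(x$products), x$products),
              collapse = ", "), "\n")
  invisible(x)
}

#' Load the packaged macroscopic chemostat measurements
#'
#' Glucose-limited chemostat at D = 0.1 1/h under 21% (normoxic), 11%
#' (oxygen-limited) or 8% (hypoxic) inlet oxygen. The feed glucose
#' concentration is back-computed as biomass / yield (residual glucose is
#' below detection under carbon limitation) and marked as derived.
#'
#' @param condition oxygenation condition.
#' @param strain kept for interface symmetry; the packaged macroscopic data
#'   are from the expressing strain.
#' @return a `ChemostatState`.
#' @export
packagedChemostat <- function(condition = c("normoxic", "oxygen_limited",
                                            "hypoxic"),
                              strain = "expressing") {
  condition <- match.arg(condition)
  tab <- utils::read.delim(.fixture_path("chemostat_macroscopic.tsv"),
                           stringsAsFactors = FALSE)
  sel <- tab[tab$condition == condition, ]
  g <- function(q) sel$value[sel$quantity == q][1]
  gs <- function(q) sel$sd[sel$quantity == q][1]
  X <- g("biomass"); yield <- g("biomass_yield")
  feed <- X / yield
  # sd of the derived feed by first-order propagation
  feed_sd <- feed * sqrt((gs("biomass") / X)^2 +
                         (gs("biomass_yield") / yield)^2)
  prods <- c(ethanol = g("ethanol"), glycerol = g("glycerol"),
             arabitol = g("arabitol"))
  # the feed is derived as X / yield, so the biomass term cancels in
  # q_glucose = D feed / X = D / yield; propagate D and yield only
  q_glc_rel <- sqrt((gs("dilution_rate") / g("dilution_rate"))^2 +
                    (gs("biomass_yield") / yield)^2)
  chemostatState(
    dilution_rate = g("dilution_rate"), feed_glucose = feed,
    residual_glucose = 0, biomass = X, products = prods,
    OUR = g("OUR"), CER = g("CER"),
    sds = list(dilution_rate = gs("dilution_rate"), biomass = gs("biomass"),
               feed_glucose = feed_sd, q_glucose_rel = q_glc_rel,
               products = c(ethanol = gs("ethanol"),
                            glycerol = gs("glycerol"),
                            arabitol = gs("arabitol"))))
}

#' Construct a rate table
#'
#' @param rates named numeric vector of specific rates
#'   (mmol gDCW^-1 h^-1), keyed by reaction id.
#' @param sds named numeric vector of standard deviations; if missing, a
#'   relative sd of `rel_sd` with an absolute floor `sd_floor` is applied.
#' @param rel_sd default relative standard deviation (0.05).
#' @param sd_floor absolute sd floor for near-zero rates
#'   (mmol gDCW^-1 h^-1).
#' @return a [RateTable-class].
#' @export
rateTable <- function(rates, sds = NULL, rel_sd = 0.05, sd_floor = 0.005) {
  if (is.null(sds))
    sds <- pmax(abs(rates) * rel_sd, sd_floor)
  sds <- sds[names(rates)]
  new("RateTable", rates = rates, sds = stats::setNames(sds, names(rates)))
}

#' @describeIn RateTable-class the rate vector.
#' @param object a [RateTable-class].
#' @export
rateValues <- function(object) object@rates

#' @describeIn RateTable-class the standard deviations.
#' @export
rateSds <- function(object) object@sds

setMethod("show", "RateTable", function(object) {
  cat(sprintf("RateTable: %d rates (%s)\n", length(object@rates),
              object@units))
  df <- data.frame(rate = object@rates, sd = object@sds)
  print(utils::head(df, 8))
  if (length(object@rates) > 8) cat("  ...\n")
})

#' Specific exchange rates from a chemostat state
#'
#' Converts broth concentrations into specific rates:
#' `q_glucose = D (feed - residual) / X` and `q_product = D conc / X`,
#' in mmol gDCW^-1 h^-1 using the supplied molar masses. OUR and CER are
#' passed through as attributes (diagnostics; the model balances neither O2
#' nor CO2). Standard deviations are propagated first-order from the
#' concentration and biomass sds where available, with a 5% relative
#' default.
#'
#' @param state a `ChemostatState`.
#' @param molar_masses named vector of molar masses (g/mol); must cover
#'   glucose and every product.
#' @param reaction_ids named character mapping species -> reaction id
#'   (defaults match [buildNetwork()]).
#' @return a [RateTable-class] of exchange rates.
#' @examples
#' st <- packagedChemostat("hypoxic")
#' rateValues(specificRates(st))[["adh_etoh"]]  # ~1.18 mmol/gDCW/h ethanol
#' @export
specificRates <- function(state, molar_masses = defaultMolarMasses(),
                          reaction_ids = c(glucose = "glc_upt",
                                           ethanol = "adh_etoh",
                                           glycerol = "gol_ex",
                                           arabitol = "ara_ex")) {
  stopifnot(inherits(state, "ChemostatState"))
  D <- state$dilution_rate; X <- state$biomass
  need <- c("glucose", names(state$products))
  miss <- setdiff(need, names(molar_masses))
  if (length(miss))
    stop("missing molar mass for: ", paste(miss, collapse = ", "))
  rel <- function(v, s) if (is.null(s) || !is.finite(s) || v == 0) 0 else s / v
  rates <- sds <- numeric(); ids <- character()
  q_glc <- D * (state$feed_glucose - state$residual_glucose) / X /
    molar_masses[["glucose"]] * 1000
  glc_rel <- if (!is.null(state$sds$q_glucose_rel))
    state$sds$q_glucose_rel
  else sqrt(rel(state$feed_glucose, state$sds$feed_glucose)^2 +
            rel(X, state$sds$biomass)^2 +
            rel(D, state$sds$dilution_rate)^2)
  rates <- c(rates, q_glc); sds <- c(sds, abs(q_glc) * glc_rel)
  ids <- c(ids, reaction_ids[["glucose"]])
  for (sp in names(state$products)) {
    q <- D * state$products[[sp]] / X / molar_masses[[sp]] * 1000
    r <- sqrt(rel(state$products[[sp]], state$sds$products[[sp]])^2 +
              rel(X, state$sds$biomass)^2 +
              rel(D, state$sds$dilution_rate)^2)
    rates <- c(rates, q); sds <- c(sds, abs(q) * r)
    if (!sp %in% names(reaction_ids))
      stop("no reaction id mapping for product '", sp, "'")
    ids <- c(ids, reaction_ids[[sp]])
  }
  names(rates) <- names(sds) <- ids
  out <- rateTable(rates, sds = pmax(sds, 0.005))
  attr(out, "OUR") <- state$OUR
  attr(out, "CER") <- state$CER
  out
}

#' Synthetic anabolic precursor demand coefficients
#'
#' Order-of-magnitude yeast biomass precursor demands (mmol per gDCW),
#' summing to roughly 43 mmol of precursor carbon per gram dry weight
#' (biomass elemental carbon is about 40 mmol C/gDCW). These are synthetic
#' defaults standing in for condition-specific measured biomass
#' composition, and can be replaced wholesale.
#'
#' @return named numeric vector, mmol precursor per gDCW, keyed by drain
#'   reaction id.
#' @export
defaultDrainCoefficients <- function() {
  c(bm_g6p = 2.00, bm_f6p = 0.10, bm_t3p = 1.00, bm_p5p = 0.45,
    bm_e4p = 0.27, bm_pep = 1.00, bm_pyr_cyt = 1.40, bm_pyr_mit = 1.00,
    bm_accoa_cyt = 1.00, bm_accoa_mit = 0.40, bm_oaa_cyt = 1.00,
    bm_oaa_mit = 0.50, bm_akg = 1.10)
}

#' Anabolic drain rates at a given growth rate
#'
#' Precursor depletion to biosynthesis: coefficient times the specific
#' growth rate (equal to D at steady state).
#'
#' @param D dilution rate (1/h).
#' @param coefficients mmol precursor per gDCW
#'   (default [defaultDrainCoefficients()]).
#' @param rel_sd relative sd applied to the drain rates (default 5%).
#' @return a [RateTable-class] of drain rates.
#' @export
drainRates <- function(D, coefficients = defaultDrainCoefficients(),
                       rel_sd = 0.05) {
  stopifnot(D > 0)
  rateTable(coefficients * D, rel_sd = rel_sd, sd_floor = 1e-4)
}

#' Merge rate tables
#' @param ... [RateTable-class] objects with disjoint names.
#' @return a combined [RateTable-class].
#' @export
combineRates <- function(...) {
  tabs <- list(...)
  rates <- do.call(c, lapply(tabs, rateValues))
  sds <- do.call(c, lapply(tabs, rateSds))
  if (anyDuplicated(names(rates))) stop("duplicate rate ids in combination")
  new("RateTable", rates = rates, sds = sds)
}

#' Unlabelled biomass fraction after a labelling switch
#'
#' Fraction of the harvested biomass synthesized before the switch to
#' 13C-labelled feed, following first-order chemostat wash-out kinetics:
#' `exp(-D t)`. Harvesting after one residence time (`t = 1/D`) leaves a
#' fraction `exp(-1)` (about 0.368) of pre-switch biomass.
#'
#' @param D dilution rate (1/h), `>= 0`.
#' @param t time since the labelled-feed switch (h), `>= 0`.
#' @return fraction in (0, 1\].
#' @examples
#' unlabeledFraction(0.1, 10)  # one residence time: exp(-1)
#' @export
unlabeledFraction <- function(D, t) {
  if (any(D < 0) || any(t < 0)) stop("D and t must be non-negative")
  exp(-D * t)
}

#' Carbon recovery diagnostic
#'
#' Fraction of consumed glucose carbon recovered in biomass, CO2 and
#' excreted products:
#' `(q_biomassC + CER + sum_i q_i * C_i) / (q_glucose * 6)`.
#'
#' @param state a `ChemostatState` (supplies CER).
#' @param rates a [RateTable-class] holding at least the glucose uptake and
#'   product excretion rates.
#' @param biomass_carbon biomass elemental carbon (mmol C per gDCW, default
#'   40.6, i.e. 24.6 g biomass per C-mol).
#' @param carbon named carbon counts per product reaction id; defaults
#'   match [buildNetwork()].
#' @return carbon recovery as a fraction; `NA` with a warning when glucose
#'   consumption is zero.
#' @export
carbonRecovery <- function(state, rates, biomass_carbon = 40.6,
                           carbon = c(glc_upt = 6, adh_etoh = 2,
                                      gol_ex = 3, ara_ex = 5)) {
  r <- rateValues(rates)
  q_glc <- if ("glc_upt" %in% names(r)) r[["glc_upt"]] else 0
  if (q_glc <= 0) {
    warning("zero glucose consumption: carbon recovery undefined")
    return(NA_real_)
  }
  prod_ids <- setdiff(intersect(names(carbon), names(r)), "glc_upt")
  prod_c <- sum(r[prod_ids] * carbon[prod_ids])
  bio_c <- state$dilution_rate * biomass_carbon
  co2 <- if (is.finite(state$CER)) state$CER else 0
  (bio_c + co2 + prod_c) / (q_glc * carbon[["glc_upt"]])
}
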