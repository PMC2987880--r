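#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Compartmented stoichiometric network model
#'
#' Holds the central-carbon reaction network of *Pichia pastoris* for one
#' oxygenation condition. Metabolites live in the cytosol, the mitochondria or
#' outside the cell; only balanced metabolites contribute mass-balance rows
#' (CO2, external species and biomass sinks are unbalanced). Reactions carry
#' signed stoichiometric coefficients, a reversibility flag, a pathway
#' category and, where a reaction plays a named role in the METAFoR flux-ratio
#' constraints, a ratio alias (`x3`, `x9`, `x10`, `x11`, `x16`, `x17`, `x23`,
#' `x24`, `x23star`, `x24star`).
#'
#' @slot metabolites `data.frame` with columns `id`, `name`, `compartment`
#'   (`"cytosol"`, `"mitochondria"` or `"external"`), `balanced` (logical) and
#'   `carbon_count` (non-negative integer).
#' @slot reactions `data.frame` with columns `id`, `name`, `reversible`,
#'   `category` (one of `"glycolysis"`, `"ppp"`, `"tca"`, `"fermentative"`,
#'   `"transport"`, `"anabolic"`, `"exchange"`), `ratio_alias` (`NA` or an
#'   alias symbol) and a list-column `stoich` of named numeric coefficient
#'   vectors (negative = consumed, positive = produced).
#' @slot condition one of `"normoxic"`, `"oxygen_limited"`, `"hypoxic"`.
#'
#' @seealso [buildNetwork()], [stoichiometricMatrix()], [validateNetwork()]
#' @export
setClass("NetworkModel",
  representation(
    metabolites = "data.frame",
    reactions   = "data.frame",
    condition   = "character"
  )
)

.mfa_conditions <- c("normoxic", "oxygen_limited", "hypoxic")
.mfa_compartments <- c("cytosol", "mitochondria", "external")
.mfa_categories <- c("glycolysis", "ppp", "tca", "fermentative",
                     "transport", "anabolic", "exchange")
.mfa_aliases <- c("x3", "x9", "x10", "x11", "x16", "x17",
                  "x23", "x23star", "x24", "x24star")

setValidity("NetworkModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (!all(met$compartment %in% .mfa_compartments))
    msg <- c(msg, "unknown metabolite compartment")
  if (any(met$balanced & met$compartment == "external"))
    msg <- c(msg, "balanced metabolites must not be external")
  if (any(met$carbon_count < 0)) msg <- c(msg, "negative carbon_count")
  if (!all(rxn$category %in% .mfa_categories))
    msg <- c(msg, "unknown reaction category")
  if (length(object@condition) != 1L ||
      !object@condition %in% .mfa_conditions)
    msg <- c(msg, "condition must be one of normoxic/oxygen_limited/hypoxic")
  al <- rxn$ratio_alias[!is.na(rxn$ratio_alias)]
  if (!all(al %in% .mfa_aliases)) msg <- c(msg, "unknown ratio alias")
  if (anyDuplicated(al)) msg <- c(msg, "ratio alias used more than once")
  for (i in seq_len(nrow(rxn))) {
    st <- rxn$stoich[[i]]
    if (length(st) == 0L)
      msg <- c(msg, sprintf("reaction '%s' has empty stoichiometry", rxn$id[i]))
    bad <- setdiff(names(st), met$id)
    if (length(bad))
      msg <- c(msg, sprintf("reaction '%s' references unknown metabolite(s): %s",
                            rxn$id[i], paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' METAFoR flux-ratio set
#'
#' Measured metabolic flux ratios for one strain/condition, as fractions in
#' \[0, 1\] with standard deviations. Ratio `a` (Oaa_mit from Oaa_cyt) and `c`
#' (Oaa_cyt from Pep, the anaplerotic ratio) are only determinable under
#' oxygen limitation and hypoxia; `b` is the normoxic net-transport analogue
#' of `a`; `d` is the upper bound on the fraction of Pep originating from the
#' pentose-phosphate pool and enters the system as an inequality.
#'
#' @slot condition oxygenation condition the ratios apply to.
#' @slot ratios named numeric vector with elements `a`, `b`, `c`, `d`
#'   (absent ratios are `NA`).
#' @slot sds named numeric vector of standard deviations, same names.
#' @slot source free-text provenance string.
#' @slot annotations optional `data.frame` of diagnostic ratios that are not
#'   used as constraints (carried along for reporting only).
#' @export
setClass("RatioSet",
  representation(
    condition   = "character",
    ratios      = "numeric",
    sds         = "numeric",
    source      = "character",
    annotations = "data.frameOrNULL"
  ),
  prototype(annotations = NULL, source = "")
)

setValidity("RatioSet", function(object) {
  msg <- character()
  r <- object@ratios; s <- object@sds
  if (!identical(sort(names(r)), c("a", "b", "c", "d")))
    msg <- c(msg, "ratios must be named a, b, c, d")
  if (!identical(sort(names(s)), c("a", "b", "c", "d")))
    msg <- c(msg, "sds must be named a, b, c, d")
  if (length(object@condition) != 1L ||
      !object@condition %in% .mfa_conditions)
    msg <- c(msg, "invalid condition")
  pres <- names(r)[!is.na(r)]
  if (any(r[pres] < 0 | r[pres] > 1))
    msg <- c(msg, "present ratios must lie in [0, 1]")
  # measured sets carry sd > 0; computed sets leave sd NA
  if (any(!is.na(s) & s <= 0))
    msg <- c(msg, "ratio sds must be > 0 where given")
  if (object@condition == "normoxic") {
    if (any(c("a", "c") %in% pres))
      msg <- c(msg, "a and c are not determinable under normoxia")
  } else {
    if ("b" %in% pres)
      msg <- c(msg, "b applies to the normoxic condition only")
  }
  if (length(msg)) msg else TRUE
})

#' Measured specific-rate table
#'
#' Specific exchange and anabolic-drain rates (mmol per gram dry cell weight
#' per hour) with standard deviations, keyed by reaction id of the target
#' network model. This is the measured part of the right-hand side of the
#' assembled flux-balancing system.
#'
#' @slot rates named numeric vector, mmol gDCW^-1 h^-1.
#' @slot sds named numeric vector of standard deviations (> 0), same names.
#' @slot units character scalar, informational (default
#'   `"mmol/gDCW/h"`).
#' @export
setClass("RateTable",
  representation(rates = "numeric", sds = "numeric", units = "character"),
  prototype(units = "mmol/gDCW/h")
)

setValidity("RateTable", function(object) {
  msg <- character()
  if (is.null(names(object@rates)) || anyDuplicated(names(object@rates)))
    msg <- c(msg, "rates must have unique names")
  if (!identical(names(object@rates), names(object@sds)))
    msg <- c(msg, "rates and sds must share names and order")
  if (any(!is.finite(object@rates))) msg <- c(msg, "non-finite rate")
  if (any(!is.finite(object@sds) | object@sds <= 0))
    msg <- c(msg, "sds must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' Assembled linear flux-balancing system
#'
#' The stacked least-squares system `N x = b`: balanced-metabolite mass
#' balances (rhs 0), measurement rows pinning exchange/drain fluxes to their
#' measured values, and METAFoR ratio equality rows (rhs 0), plus the single
#' pentose-phosphate inequality row (`row . x <= 0`) and per-reaction lower
#' bounds (0 for irreversible reactions, -Inf otherwise).
#'
#' @slot N numeric matrix, one column per reaction.
#' @slot b numeric right-hand side.
#' @slot weights per-row weights applied to the least-squares objective
#'   (1/sd under whitened weighting, 1 otherwise).
#' @slot row_type character per row: `"balance"`, `"measurement"`, `"ratio"`.
#' @slot row_id identifier per row (metabolite id, reaction id, or ratio
#'   name).
#' @slot row_sd per-row measurement standard deviation (`NA` for balance
#'   rows).
#' @slot inequality numeric row vector over reactions (the Eq.-8 style
#'   constraint), or length-0 when no `d` ratio is present.
#' @slot inequality_rhs right-hand side of the inequality (0).
#' @slot lower per-reaction lower bounds.
#' @slot model the [NetworkModel-class] the system was assembled from.
#' @slot ratios the [RatioSet-class] used.
#' @slot weighting `"whitened"` or `"unweighted"`.
#' @slot strict logical; if `TRUE` measurement rows are pinned exactly.
#' @export
setClass("AssembledSystem",
  representation(
    N = "matrix", b = "numeric", weights = "numeric",
    row_type = "character", row_id = "character", row_sd = "numeric",
    inequality = "numeric", inequality_rhs = "numeric",
    lower = "numeric", model = "NetworkModel", ratios = "RatioSet",
    weighting = "character", strict = "logical"
  )
)

setValidity("AssembledSystem", function(object) {
  msg <- character()
  n <- nrow(object@N)
  if (length(object@b) != n || length(object@weights) != n ||
      length(object@row_type) != n || length(object@row_id) != n ||
      length(object@row_sd) != n)
    msg <- c(msg, "row annotations must match nrow(N)")
  if (length(object@lower) != ncol(object@N))
    msg <- c(msg, "lower bounds must match ncol(N)")
  if (length(object@inequality) &&
      length(object@inequality) != ncol(object@N))
    msg <- c(msg, "inequality row must match ncol(N)")
  if (any(object@b[object@row_type == "ratio"] != 0))
    msg <- c(msg, "ratio rows must have rhs 0")
  if (any(object@b[object@row_type == "balance"] != 0))
    msg <- c(msg, "balance rows must have rhs 0")
  if (length(msg)) msg else TRUE
})

#' Estimated flux distribution
#'
#' Result of the bounded, inequality-constrained least-squares solve: the
#' flux vector (mmol gDCW^-1 h^-1), per-row residuals, the weighted sum of
#' squared residuals, residual degrees of freedom, the active-constraint
#' report and fluxes normalized to the specific glucose uptake rate.
#'
#' @slot x named flux vector.
#' @slot residuals per-row residuals of `N x - b` (unweighted scale).
#' @slot weighted_ssr weighted sum of squared residuals over measurement and
#'   ratio rows.
#' @slot dof residual degrees of freedom (rows minus free directions).
#' @slot active_bounds reaction ids whose lower bound is active.
#' @slot inequality_active logical, whether the pentose-phosphate inequality
#'   is active at the solution.
#' @slot normalized fluxes divided by glucose uptake.
#' @slot kkt_residual projected-gradient norm at the solution (optimality
#'   certificate, tolerance 1e-10 on the normalized scale).
#' @slot system the [AssembledSystem-class] that was solved.
#' @export
setClass("FluxSolution",
  representation(
    x = "numeric", residuals = "numeric", weighted_ssr = "numeric",
    dof = "numeric", active_bounds = "character",
    inequality_active = "logical", normalized = "numeric",
    kkt_residual = "numeric", system = "AssembledSystem"
  )
)

#' Flux uncertainty report
#'
#' Fisher-Information based uncertainty of the estimated fluxes: the
#' estimator sensitivity matrix W (d flux / d measured parameter), the
#' diagonal measurement variance-covariance matrix C, the information matrix,
#' per-flux standard deviations and Student-t confidence intervals.
#'
#' @slot W sensitivity matrix, fluxes x parameters.
#' @slot C diagonal variance-covariance matrix of the measured parameters.
#' @slot FIM information matrix (pseudo-inverse of the flux covariance).
#' @slot covariance flux covariance matrix `W C W^T`.
#' @slot sigma named per-flux standard deviations.
#' @slot ci `data.frame` with columns `flux_id`, `estimate`, `sigma`,
#'   `ci_low`, `ci_high`, `flag`.
#' @slot alpha significance level.
#' @slot v degrees of freedom used for the t quantile (`Inf` = normal).
#' @slot flags per-flux character flags (`"active_bound"` etc.).
#' @export
setClass("UncertaintyReport",
  representation(
    W = "matrix", C = "matrix", FIM = "matrix", covariance = "matrix",
    sigma = "numeric", ci = "data.frame", alpha = "numeric", v = "numeric",
    flags = "character"
  )
)

#' Synthetic measurement dataset
#'
#' A ground-truth feasible flux distribution together with the noisy
#' measurements (rates and METAFoR ratios) simulated from it, plus the noise
#' specification and seed so the dataset is exactly reproducible.
#'
#' @slot truth named ground-truth flux vector satisfying the mass balances
#'   and bounds.
#' @slot rates noisy [RateTable-class].
#' @slot ratios noisy [RatioSet-class].
#' @slot noise_spec list of noise magnitudes used.
#' @slot seed integer seed the dataset was generated from.
#' @slot model the [NetworkModel-class] the truth lives on.
#' @export
setClass("SyntheticDataset",
  representation(
    truth = "numeric", rates = "RateTable", ratios = "RatioSet",
    noise_spec = "list", seed = "numeric", model = "NetworkModel"
  )
)
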