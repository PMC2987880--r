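#' Run the full flux-analysis pipeline on packaged measurements
#'
#' Convenience wrapper: builds the condition-specific network, derives the
#' specific exchange rates from the packaged chemostat record, adds the
#' default anabolic drains, loads the packaged METAFoR ratios, assembles
#' and solves the system, and computes uncertainty and branch fractions.
#'
#' @param condition oxygenation condition.
#' @param strain `"expressing"` or `"control"` (selects the ratio set).
#' @param weighting row weighting mode, see [assembleSystem()].
#' @param drain_coefficients anabolic demands
#'   (default [defaultDrainCoefficients()], synthetic yeast values).
#' @param alpha CI significance level.
#' @return list with `model`, `rates`, `ratios`, `system`, `solution`,
#'   `uncertainty`, `branch`, `carbon_recovery`.
#' @examples
#' \donttest{
#' res <- runMFA("hypoxic")
#' normalizedFluxes(res$solution)[["adh_etoh"]]
#' }
#' @export
runMFA <- function(condition = c("normoxic", "oxygen_limited", "hypoxic"),
                   strain = c("expressing", "control"),
                   weighting = "whitened",
                   drain_coefficients = defaultDrainCoefficients(),
                   alpha = 0.05) {
  condition <- match.arg(condition)
  strain <- match.arg(strain)
  model <- buildNetwork(condition)
  state <- packagedChemostat(condition)
  exch <- specificRates(state)
  drains <- drainRates(state$dilution_rate, drain_coefficients)
  rates <- combineRates(exch, drains)
  ratios <- packagedRatios(strain, condition)
  system <- assembleSystem(model, rates, ratios, weighting = weighting)
  solution <- solveFluxes(system)
  uncertainty <- fluxUncertainty(system, solution, alpha = alpha)
  branch <- branchFractions(solution, model)
  list(model = model, rates = rates, ratios = ratios, system = system,
       solution = solution, uncertainty = uncertainty, branch = branch,
       carbon_recovery = carbonRecovery(state, rates))
}

#' Write flux estimates and the analysis report to files
#'
#' Writes `fluxes.tsv` (flux_id, value, sd, ci_low, ci_high, normalized)
#' and `report.json` (residuals, dof, active set, branch fractions, carbon
#' recovery) into `dir`.
#'
#' @param result a list as returned by [runMFA()], or at least containing
#'   `solution` and `uncertainty`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeFluxReport <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sol <- result$solution; unc <- result$uncertainty
  tab <- data.frame(flux_id = names(sol@x), value = unname(sol@x),
                    sd = unname(unc@sigma[names(sol@x)]),
                    ci_low = unc@ci$ci_low[match(names(sol@x),
                                                 unc@ci$flux_id)],
                    ci_high = unc@ci$ci_high[match(names(sol@x),
                                                   unc@ci$flux_id)],
                    normalized = unname(sol@normalized),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(dir, "fluxes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(
    condition = condition(sol@system@model),
    weighted_ssr = sol@weighted_ssr,
    dof = sol@dof,
    kkt_residual = sol@kkt_residual,
    active_bounds = sol@active_bounds,
    inequality_active = sol@inequality_active,
    residuals = as.list(sol@residuals),
    branch_fractions = result$branch,
    carbon_recovery = result$carbon_recovery)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write simulated measurements in the solver's input dialect
#'
#' Writes `rates.tsv` (reaction_id, value, sd, units) and `ratios.tsv`
#' (condition, ratio, value, sd) for a synthetic dataset, plus the network
#' as JSON.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rv <- rateValues(dataset@rates); rs <- rateSds(dataset@rates)
  utils::write.table(
    data.frame(reaction_id = names(rv), value = unname(rv),
               sd = unname(rs), units = "mmol/gDCW/h"),
    file.path(dir, "rates.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  vals <- dataset@ratios@ratios
  keep <- !is.na(vals)
  utils::write.table(
    data.frame(condition = dataset@ratios@condition,
               ratio = names(vals)[keep], value = unname(vals[keep]),
               sd = unname(dataset@ratios@sds[keep])),
    file.path(dir, "ratios.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeNetwork(dataset@model, file.path(dir, "network.json"))
  invisible(dir)
}

#' Read a rates TSV (reaction_id, value, sd)
#' @param path file path.
#' @return a [RateTable-class].
#' @export
readRates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("reaction_id", "value", "sd"))
    if (!col %in% names(tab)) stop("rates file missing column '", col, "'")
  rateTable(stats::setNames(tab$value, tab$reaction_id),
            sds = stats::setNames(tab$sd, tab$reaction_id))
}

#' Read a ratios TSV (condition, ratio, value, sd)
#' @param path file path.
#' @param condition condition to select (default: the file's single
#'   condition).
#' @return a [RatioSet-class].
#' @export
readRatios <- function(path, condition = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("condition", "ratio", "value", "sd"))
    if (!col %in% names(tab)) stop("ratios file missing column '", col, "'")
  if (is.null(condition)) {
    condition <- unique(tab$condition)
    if (length(condition) != 1L)
      stop("ratios file has several conditions; pick one")
  }
  sel <- tab[tab$condition == condition & tab$ratio %in% c("a", "b", "c", "d"), ]
  g <- function(r) {
    i <- match(r, sel$ratio)
    if (is.na(i)) c(NA_real_, NA_real_) else c(sel$value[i], sel$sd[i])
  }
  a <- g("a"); b <- g("b"); cc <- g("c"); d <- g("d")
  RatioSet(condition, a = a[1], sd_a = a[2], b = b[1], sd_b = b[2],
           c = cc[1], sd_c = cc[2], d = d[1], sd_d = d[2],
           source = path)
}
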