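#' Construct a METAFoR ratio set
#'
#' @param condition oxygenation condition the ratios apply to.
#' @param a,b,c,d ratio values as fractions in \[0, 1\]; `NA` = absent.
#'   `a` and `c` require a non-normoxic condition, `b` requires normoxia.
#' @param sd_a,sd_b,sd_c,sd_d standard deviations (fractions), required for
#'   every present ratio.
#' @param source free-text provenance.
#' @param annotations optional `data.frame` of diagnostic ratios carried
#'   along but never used as constraints.
#' @return a validated [RatioSet-class].
#' @examples
#' RatioSet("hypoxic", a = 0.55, sd_a = 0.03, c = 0.64, sd_c = 0.04,
#'          d = 0.15, sd_d = 0.07)
#' @export
RatioSet <- function(condition, a = NA_real_, b = NA_real_, c = NA_real_,
                     d = NA_real_, sd_a = NA_real_, sd_b = NA_real_,
                     sd_c = NA_real_, sd_d = NA_real_, source = "",
                     annotations = NULL) {
  new("RatioSet", condition = condition,
      ratios = c(a = a, b = b, c = c, d = d),
      sds = c(a = sd_a, b = sd_b, c = sd_c, d = sd_d),
      source = source, annotations = annotations)
}

#' An empty ratio set (no constraints)
#' @param condition oxygenation condition.
#' @return a [RatioSet-class] with all ratios absent.
#' @export
emptyRatioSet <- function(condition) RatioSet(condition, source = "empty")

setMethod("condition", "RatioSet", function(object) object@condition)

#' @describeIn RatioSet-class present (non-`NA`) ratio values.
#' @param object a [RatioSet-class].
#' @export
ratioValues <- function(object) object@ratios[!is.na(object@ratios)]

#' @describeIn RatioSet-class standard deviations of the present ratios.
#' @export
ratioSds <- function(object) object@sds[!is.na(object@ratios)]

setMethod("show", "RatioSet", function(object) {
  cat(sprintf("RatioSet (%s)%s\n", object@condition,
              if (nzchar(object@source)) paste0(" [", object@source, "]")
              else ""))
  pres <- !is.na(object@ratios)
  if (!any(pres)) { cat("  (no ratios)\n"); return(invisible(NULL)) }
  for (nm in names(object@ratios)[pres])
    cat(sprintf("  %s = %.3f +- %s\n", nm, object@ratios[[nm]],
                ifelse(is.na(object@sds[[nm]]), "NA",
                       sprintf("%.3f", object@sds[[nm]]))))
})

.alias_flux <- function(fluxes, model, alias) {
  am <- aliasMap(model)
  if (!alias %in% names(am))
    stop("model is missing ratio alias '", alias, "'")
  unname(fluxes[[am[[alias]]]])
}

.safe_ratio <- function(num, den, name) {
  if (!is.finite(num) || !is.finite(den))
    stop("non-finite alias flux while computing ratio '", name, "'")
  if (abs(den) < .Machine$double.eps * 64)
    stop("undefined ratio '", name, "': zero denominator")
  num / den
}

setMethod("computeRatios", signature(fluxes = "numeric", model = "NetworkModel"),
  function(fluxes, model, ...) {
    cond <- model@condition
    x16 <- .alias_flux(fluxes, model, "x16")
    x17 <- .alias_flux(fluxes, model, "x17")
    x3  <- .alias_flux(fluxes, model, "x3")
    x9  <- .alias_flux(fluxes, model, "x9")
    x10 <- .alias_flux(fluxes, model, "x10")
    x11 <- .alias_flux(fluxes, model, "x11")
    a <- b <- cc <- NA_real_
    if (cond == "normoxic") {
      x23s <- .alias_flux(fluxes, model, "x23star")
      b <- .safe_ratio(x23s, x23s + x16, "b")
    } else {
      x23 <- .alias_flux(fluxes, model, "x23")
      x24 <- .alias_flux(fluxes, model, "x24")
      a  <- .safe_ratio(x23, x23 + x16, "a")
      cc <- .safe_ratio(x17, x17 + x24, "c")
    }
    d <- .safe_ratio(x9 + 2 * x11 + 3 * x10, 2 * x3 + x9 + x10, "d")
    vals <- c(a = a, b = b, c = cc, d = d)
    out <- vals[!is.na(vals)]
    bad <- names(out)[out < 0 | out > 1]
    if (length(bad))
      warning("ratio(s) outside [0, 1]: ",
              paste(sprintf("%s = %.4g", bad, out[bad]), collapse = ", "),
              " (reported raw; check the alias mapping or flux signs)")
    # out-of-range values are reported raw via the attribute; the validated
    # object clips so downstream constraint assembly stays well-defined
    clipped <- pmin(pmax(vals, 0), 1)
    rs <- new("RatioSet", condition = cond, ratios = clipped,
              sds = c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_),
              source = "computed", annotations = NULL)
    attr(rs, "raw") <- vals
    rs
  })

setMethod("computeRatios", signature(fluxes = "FluxSolution", model = "NetworkModel"),
  function(fluxes, model, ...) computeRatios(fluxes@x, model, ...))

# one equality row over the reaction columns: flux_num * (1 - r) - flux_den * r
.ratio_row <- function(n, cols, num_id, den_id, r) {
  row <- stats::setNames(numeric(length(cols)), cols)
  row[num_id] <- 1 - r
  row[den_id] <- -r
  row
}

setMethod("assembleConstraintRows",
  signature(ratios = "RatioSet", model = "NetworkModel"),
  function(ratios, model) {
    cond <- model@condition
    if (ratios@condition != cond)
      stop("ratio set is for condition '", ratios@condition,
           "' but model is '", cond, "'")
    am <- aliasMap(model)
    need <- function(alias) {
      if (!alias %in% names(am))
        stop("model is missing ratio alias '", alias, "'")
      am[[alias]]
    }
    cols <- reactionIds(model)
    vals <- ratios@ratios
    sds <- ratios@sds
    rows <- list(); wts <- numeric(); rn <- character()
    add <- function(name, num_alias, den_alias) {
      r <- vals[[name]]
      row <- .ratio_row(length(cols), cols, need(num_alias), need(den_alias), r)
      rows[[length(rows) + 1L]] <<- row
      sd <- sds[[name]]
      wts <<- c(wts, if (is.finite(sd) && sd > 0) 1 / sd else 1)
      rn <<- c(rn, name)
    }
    if (!is.na(vals[["a"]])) add("a", "x23", "x16")
    if (!is.na(vals[["b"]])) add("b", "x23star", "x16")
    if (!is.na(vals[["c"]])) add("c", "x17", "x24")
    eq <- if (length(rows)) do.call(rbind, rows) else
      matrix(0, 0, length(cols), dimnames = list(NULL, cols))
    rownames(eq) <- rn
    ineq <- NULL
    if (!is.na(vals[["d"]])) {
      d <- vals[["d"]]
      ineq <- stats::setNames(numeric(length(cols)), cols)
      ineq[need("x9")] <- 1 - d
      ineq[need("x11")] <- 2
      ineq[need("x10")] <- 3 - d
      ineq[need("x3")] <- -2
    }
    list(equality_matrix = eq,
         equality_rhs = rep(0, nrow(eq)),
         row_names = rn,
         inequality_row = ineq,
         inequality_rhs = 0,
         row_weights = wts)
  })

# ---- packaged fixtures -------------------------------------------------

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "PichiaMFA")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install use
  if (!file.exists(p)) stop("packaged fixture not found: ", file)
  p
}

#' Load the packaged METAFoR ratio measurements
#'
#' Returns the published flux-ratio measurements for one strain and
#' oxygenation condition as a [RatioSet-class] (fractions with standard
#' deviations). The constraint ratios are `a` (Oaa_mit from Oaa_cyt), `b`
#' (normoxic net-transport analogue, from the Oaa_mit-from-Pep measurement),
#' `c` (Oaa_cyt from Pep) and `d` (Pep from pentose phosphates, upper
#' bound); the remaining published ratios (transketolase/transaldolase
#' reversibility, serine/glycine one-carbon exchange, PEP carboxykinase and
#' malic-enzyme bounds) are attached as annotations only.
#'
#' @param strain `"expressing"` (Fab-producing) or `"control"`.
#' @param condition `"normoxic"`, `"oxygen_limited"` or `"hypoxic"`.
#' @return a [RatioSet-class].
#' @examples
#' packagedRatios("expressing", "normoxic")   # d = 0.50 +- 0.09
#' @export
packagedRatios <- function(strain = c("expressing", "control"),
                           condition = c("normoxic", "oxygen_limited",
                                         "hypoxic")) {
  strain <- match.arg(strain)
  condition <- match.arg(condition)
  tab <- utils::read.delim(.fixture_path("metafor_ratios.tsv"),
                           stringsAsFactors = FALSE)
  sel <- tab[tab$strain == strain & tab$condition == condition, ]
  pick <- function(ratio) {
    r <- sel[sel$ratio == ratio, ]
    if (!nrow(r) || is.na(r$value[1])) c(NA_real_, NA_real_)
    else c(r$value[1], r$sd[1])
  }
  a <- pick("a"); b <- pick("b"); cc <- pick("c"); d <- pick("d")
  ann <- sel[!sel$ratio %in% c("a", "b", "c", "d"), ]
  RatioSet(condition,
           a = a[1], sd_a = a[2], b = b[1], sd_b = b[2],
           c = cc[1], sd_c = cc[2], d = d[1], sd_d = d[2],
           source = sprintf("packaged METAFoR measurements (%s, %s)",
                            strain, condition),
           annotations = if (nrow(ann)) ann[, c("ratio", "value", "sd")]
                         else NULL)
}
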