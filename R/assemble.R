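#' Internal constructor for bare least-squares systems
#'
#' Builds an [AssembledSystem-class] directly from a matrix, right-hand
#' side and per-row sds, without a network model. Used for unconstrained
#' reference problems (all rows are measurement rows) and in tests; the
#' full pipeline uses [assembleSystem()].
#'
#' @param N coefficient matrix (column names become flux ids).
#' @param b right-hand side.
#' @param sds per-row measurement standard deviations.
#' @param lower per-column lower bounds (default unbounded).
#' @param weighting `"whitened"` or `"unweighted"`.
#' @return an [AssembledSystem-class] with no balance or ratio rows.
#' @keywords internal
#' @export
bareSystem <- function(N, b, sds = rep(1, nrow(N)),
                       lower = rep(-Inf, ncol(N)),
                       weighting = c("whitened", "unweighted")) {
  weighting <- match.arg(weighting)
  if (is.null(colnames(N))) colnames(N) <- paste0("v", seq_len(ncol(N)))
  w <- if (weighting == "whitened") 1 / sds else rep(1, nrow(N))
  dummy_model <- new("NetworkModel",
                     metabolites = data.frame(
                       id = "X", name = "X", compartment = "cytosol",
                       balanced = FALSE, carbon_count = 0L,
                       stringsAsFactors = FALSE),
                     reactions = data.frame(
                       id = colnames(N), name = colnames(N),
                       reversible = TRUE, category = "exchange",
                       ratio_alias = NA_character_,
                       stoich = I(rep(list(c(X = 1)), ncol(N))),
                       stringsAsFactors = FALSE),
                     condition = "normoxic")
  new("AssembledSystem",
      N = N, b = b, weights = w,
      row_type = rep("measurement", nrow(N)),
      row_id = paste0("m", seq_len(nrow(N))),
      row_sd = sds,
      inequality = numeric(0), inequality_rhs = 0,
      lower = stats::setNames(lower, colnames(N)),
      model = dummy_model, ratios = emptyRatioSet("normoxic"),
      weighting = weighting, strict = FALSE)
}

setMethod("assembleSystem",
  signature(model = "NetworkModel", rates = "RateTable", ratios = "RatioSet"),
  function(model, rates, ratios, weighting = c("whitened", "unweighted"),
           strict = FALSE) {
    weighting <- match.arg(weighting)
    if (ratios@condition != model@condition)
      stop("ratio set condition '", ratios@condition,
           "' does not match model condition '", model@condition, "'")
    S <- stoichiometricMatrix(model)
    ids <- reactionIds(model)
    rv <- rateValues(rates); rs <- rateSds(rates)
    unknown <- setdiff(names(rv), ids)
    if (length(unknown))
      stop("rate(s) for unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    meas <- t(vapply(names(rv), function(id) {
      row <- stats::setNames(numeric(length(ids)), ids)
      row[id] <- 1
      row
    }, numeric(length(ids))))
    cr <- assembleConstraintRows(ratios, model)
    N <- rbind(S, meas, cr$equality_matrix)
    b <- c(rep(0, nrow(S)), unname(rv), cr$equality_rhs)
    row_type <- c(rep("balance", nrow(S)),
                  rep("measurement", nrow(meas)),
                  rep("ratio", nrow(cr$equality_matrix)))
    row_id <- c(rownames(S), names(rv), cr$row_names)
    row_sd <- c(rep(NA_real_, nrow(S)), unname(rs),
                if (length(cr$row_names))
                  unname(ratioSds(ratios)[cr$row_names])
                else numeric(0))
    weights <- rep(1, nrow(N))
    if (weighting == "whitened") {
      mi <- row_type != "balance"
      weights[mi] <- 1 / row_sd[mi]
    }
    rownames(N) <- row_id
    new("AssembledSystem",
        N = N, b = b, weights = weights, row_type = row_type,
        row_id = row_id, row_sd = row_sd,
        inequality = if (is.null(cr$inequality_row)) numeric(0)
                     else cr$inequality_row,
        inequality_rhs = cr$inequality_rhs,
        lower = stats::setNames(
          ifelse(model@reactions$reversible, -Inf, 0), ids),
        model = model, ratios = ratios, weighting = weighting,
        strict = isTRUE(strict))
  })

setMethod("show", "AssembledSystem", function(object) {
  cat(sprintf(paste0("AssembledSystem: %d rows x %d reactions ",
                     "(%d balance, %d measurement, %d ratio), %s%s\n"),
              nrow(object@N), ncol(object@N),
              sum(object@row_type == "balance"),
              sum(object@row_type == "measurement"),
              sum(object@row_type == "ratio"),
              object@weighting,
              if (object@strict) ", strict measurements" else ""))
  if (length(object@inequality))
    cat("  + pentose-phosphate inequality row\n")
})
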