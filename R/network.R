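# Central-carbon network of P. pastoris: metabolite table shared by all
# condition variants. Carbon counts are per molecule; acetyl units count the
# two acetyl carbons. BIOMASS is a carbon-free sink for anabolic drains (the
# drained precursor carbon is accounted on the precursor side).
.metabolite_table <- function() {
  m <- rbind(
    c("G6P",      "glucose-6-phosphate",        "cytosol",      TRUE,  6),
    c("F6P",      "fructose-6-phosphate",       "cytosol",      TRUE,  6),
    c("T3P",      "triose-3-phosphate pool",    "cytosol",      TRUE,  3),
    c("P5P",      "pentose-5-phosphate pool",   "cytosol",      TRUE,  5),
    c("S7P",      "sedoheptulose-7-phosphate",  "cytosol",      TRUE,  7),
    c("E4P",      "erythrose-4-phosphate",      "cytosol",      TRUE,  4),
    c("Pep",      "phosphoenolpyruvate",        "cytosol",      TRUE,  3),
    c("Pyr_cyt",  "pyruvate (cytosol)",         "cytosol",      TRUE,  3),
    c("Acald",    "acetaldehyde",               "cytosol",      TRUE,  2),
    c("AcCoA_cyt","acetyl-CoA (cytosol)",       "cytosol",      TRUE,  2),
    c("Oaa_cyt",  "oxaloacetate (cytosol)",     "cytosol",      TRUE,  4),
    c("Pyr_mit",  "pyruvate (mitochondria)",    "mitochondria", TRUE,  3),
    c("AcCoA_mit","acetyl-CoA (mitochondria)",  "mitochondria", TRUE,  2),
    c("Oaa_mit",  "oxaloacetate (mitochondria)","mitochondria", TRUE,  4),
    c("AKG",      "alpha-ketoglutarate",        "mitochondria", TRUE,  5),
    c("GLC_ext",  "glucose (medium)",           "external",     FALSE, 6),
    c("ETOH_ext", "ethanol (excreted)",         "external",     FALSE, 2),
    c("GOL_ext",  "glycerol (excreted)",        "external",     FALSE, 3),
    c("ARA_ext",  "arabitol (excreted)",        "external",     FALSE, 5),
    c("CO2",      "carbon dioxide (unbalanced)","cytosol",      FALSE, 1),
    c("BIOMASS",  "biomass sink",               "external",     FALSE, 0)
  )
  data.frame(id = m[, 1], name = m[, 2], compartment = m[, 3],
             balanced = as.logical(m[, 4]),
             carbon_count = as.integer(m[, 5]),
             stringsAsFactors = FALSE)
}

.rx <- function(id, name, stoich, reversible, category, alias = NA_character_) {
  list(id = id, name = name, stoich = stoich, reversible = reversible,
       category = category, ratio_alias = alias)
}

# Precursor pools that carry an anabolic drain to biomass.
.drain_precursors <- c("G6P", "F6P", "T3P", "P5P", "E4P", "Pep",
                       "Pyr_cyt", "Pyr_mit", "AcCoA_cyt", "AcCoA_mit",
                       "Oaa_cyt", "Oaa_mit", "AKG")

.reaction_list <- function(condition) {
  r <- list(
    .rx("glc_upt", "glucose uptake",
        c(GLC_ext = -1, G6P = 1), FALSE, "exchange"),
    .rx("pgi", "phosphoglucose isomerase",
        c(G6P = -1, F6P = 1), TRUE, "glycolysis"),
    .rx("emp_up", "upper glycolysis (PFK + aldolase, lumped)",
        c(F6P = -1, T3P = 2), FALSE, "glycolysis", "x3"),
    .rx("emp_lo", "lower glycolysis (GAPDH..enolase, lumped)",
        c(T3P = -1, Pep = 1), FALSE, "glycolysis"),
    .rx("pyk", "pyruvate kinase",
        c(Pep = -1, Pyr_cyt = 1), FALSE, "glycolysis"),
    .rx("zwf", "oxidative pentose phosphate pathway (lumped)",
        c(G6P = -1, P5P = 1, CO2 = 1), FALSE, "ppp"),
    .rx("tkt1", "transketolase 1",
        c(P5P = -2, S7P = 1, T3P = 1), TRUE, "ppp", "x9"),
    .rx("tal", "transaldolase",
        c(S7P = -1, T3P = -1, E4P = 1, F6P = 1), TRUE, "ppp", "x11"),
    .rx("tkt2", "transketolase 2",
        c(P5P = -1, E4P = -1, F6P = 1, T3P = 1), TRUE, "ppp", "x10"),
    .rx("pdc", "pyruvate decarboxylase",
        c(Pyr_cyt = -1, Acald = 1, CO2 = 1), FALSE, "fermentative"),
    .rx("adh_etoh", "alcohol dehydrogenase + ethanol excretion (lumped)",
        c(Acald = -1, ETOH_ext = 1), FALSE, "fermentative"),
    .rx("acs_cyt", "cytosolic acetyl-CoA synthesis (ALD + ACS, lumped)",
        c(Acald = -1, AcCoA_cyt = 1), FALSE, "anabolic"),
    .rx("pyr_tp", "pyruvate transport into mitochondria",
        c(Pyr_cyt = -1, Pyr_mit = 1), FALSE, "transport"),
    .rx("pdh", "pyruvate dehydrogenase (PDH bypass lumped in)",
        c(Pyr_mit = -1, AcCoA_mit = 1, CO2 = 1), FALSE, "tca"),
    .rx("pyc", "pyruvate carboxylase (anaplerosis)",
        c(Pyr_cyt = -1, CO2 = -1, Oaa_cyt = 1), FALSE, "anabolic", "x17"),
    .rx("cs_idh", "citrate synthase + isocitrate span (lumped)",
        c(Oaa_mit = -1, AcCoA_mit = -1, AKG = 1, CO2 = 1), FALSE, "tca"),
    .rx("tca_mdh", "AKG -> malate -> Oaa span, malate dehydrogenase step",
        c(AKG = -1, Oaa_mit = 1, CO2 = 1), FALSE, "tca", "x16"),
    .rx("gol_ex", "glycerol branch + excretion (lumped)",
        c(T3P = -1, GOL_ext = 1), FALSE, "fermentative"),
    .rx("ara_ex", "arabitol branch from pentose phosphates + excretion",
        c(P5P = -1, ARA_ext = 1), FALSE, "fermentative")
  )
  if (condition == "normoxic") {
    r <- append(r, list(
      .rx("oaa_net", "net Oaa transport across the mitochondrial membrane",
          c(Oaa_cyt = -1, Oaa_mit = 1), TRUE, "transport", "x23star")
    ), after = 15L)
  } else {
    r <- append(r, list(
      .rx("oaa_in", "Oaa transport cytosol -> mitochondria",
          c(Oaa_cyt = -1, Oaa_mit = 1), FALSE, "transport", "x23"),
      .rx("oaa_out", "Oaa transport mitochondria -> cytosol",
          c(Oaa_mit = -1, Oaa_cyt = 1), FALSE, "transport", "x24")
    ), after = 15L)
  }
  drains <- lapply(.drain_precursors, function(p) {
    st <- c(-1, 1); names(st) <- c(p, "BIOMASS")
    .rx(paste0("bm_", tolower(p)),
        paste("anabolic drain of", p, "to biomass"),
        st, FALSE, "anabolic")
  })
  c(r, drains)
}

.reactions_df <- function(rlist) {
  data.frame(
    id = vapply(rlist, `[[`, "", "id"),
    name = vapply(rlist, `[[`, "", "name"),
    reversible = vapply(rlist, `[[`, TRUE, "reversible"),
    category = vapply(rlist, `[[`, "", "category"),
    ratio_alias = vapply(rlist, `[[`, "", "ratio_alias"),
    stoich = I(lapply(rlist, `[[`, "stoich")),
    stringsAsFactors = FALSE
  )
}

#' Build the condition-specific central-carbon network
#'
#' Constructs the compartmented stoichiometric model of *P. pastoris*
#' central carbon metabolism: glycolysis (upper and lower spans lumped),
#' the oxidative and non-oxidative pentose phosphate pathway, the TCA cycle
#' (unbranched spans lumped), the fermentative pathways (ethanol via
#' pyruvate decarboxylase and acetaldehyde), glycerol and arabitol excretion
#' branches, separate cytosolic and mitochondrial pools of pyruvate,
#' acetyl-CoA and oxaloacetate with their transmitochondrial transports, and
#' anabolic precursor drains to biomass. The glyoxylate cycle, PEP
#' carboxykinase and malic enzyme are omitted; acetyl-CoA transport (the
#' final PDH-bypass step) is omitted and the bypass flux is lumped into PDH.
#'
#' Under normoxia the oxaloacetate transport pair is replaced by a single
#' sign-free net transport reaction (alias `x23star`), giving 33 reactions;
#' the oxygen-limited and hypoxic variants carry the separate import/export
#' pair (aliases `x23`/`x24`) and 34 reactions.
#'
#' @param condition `"normoxic"`, `"oxygen_limited"` or `"hypoxic"`.
#' @return a validated [NetworkModel-class].
#' @examples
#' nReactions(buildNetwork("normoxic"))   # 33
#' nReactions(buildNetwork("hypoxic"))    # 34
#' @export
buildNetwork <- function(condition = c("normoxic", "oxygen_limited", "hypoxic")) {
  if (length(condition) != 1L && !identical(condition, .mfa_conditions))
    condition <- match.arg(condition)
  condition <- match.arg(condition)
  new("NetworkModel",
      metabolites = .metabolite_table(),
      reactions = .reactions_df(.reaction_list(condition)),
      condition = condition)
}

#' @describeIn NetworkModel-class number of reactions.
#' @param model a [NetworkModel-class].
#' @export
nReactions <- function(model) nrow(model@reactions)

#' @describeIn NetworkModel-class reaction ids in model order.
#' @export
reactionIds <- function(model) model@reactions$id

#' @describeIn NetworkModel-class the reaction table.
#' @export
reactions <- function(model) model@reactions

#' @describeIn NetworkModel-class the metabolite table.
#' @export
metabolites <- function(model) model@metabolites

#' Map ratio aliases to reaction ids
#'
#' @param model a [NetworkModel-class].
#' @return named character vector, alias -> reaction id.
#' @export
aliasMap <- function(model) {
  rxn <- model@reactions
  keep <- !is.na(rxn$ratio_alias) & nzchar(rxn$ratio_alias)
  stats::setNames(rxn$id[keep], rxn$ratio_alias[keep])
}

#' Override the ratio-alias assignment of a model
#'
#' The identities of the pentose-phosphate aliases (`x3`, `x9`, `x10`,
#' `x11`) are a modelling convention; this remaps any alias to a different
#' reaction.
#'
#' @param model a [NetworkModel-class].
#' @param aliases named character vector, alias -> reaction id.
#' @return the modified, re-validated model.
#' @export
setAliases <- function(model, aliases) {
  rxn <- model@reactions
  for (al in names(aliases)) {
    if (!al %in% .mfa_aliases) stop("unknown ratio alias: ", al)
    id <- aliases[[al]]
    if (!id %in% rxn$id) stop("unknown reaction id: ", id)
    rxn$ratio_alias[rxn$ratio_alias %in% al] <- NA_character_
    rxn$ratio_alias[rxn$id == id] <- al
  }
  model@reactions <- rxn
  validObject(model)
  model
}

setMethod("condition", "NetworkModel", function(object) object@condition)

setMethod("stoichiometricMatrix", "NetworkModel", function(model) {
  met <- model@metabolites
  rxn <- model@reactions
  bal <- met$id[met$balanced]
  S <- matrix(0, nrow = length(bal), ncol = nrow(rxn),
              dimnames = list(bal, rxn$id))
  for (j in seq_len(nrow(rxn))) {
    st <- rxn$stoich[[j]]
    keep <- names(st) %in% bal
    S[names(st)[keep], j] <- st[keep]
  }
  zero <- colSums(abs(S)) == 0
  # exchange-only columns that touch no balanced species are disconnected
  if (any(zero))
    stop("all-zero stoichiometric column(s): ",
         paste(colnames(S)[zero], collapse = ", "))
  S
})

# aliases required by the constraint set of each condition
.required_aliases <- function(condition) {
  if (condition == "normoxic")
    c("x23star", "x16", "x17", "x3", "x9", "x10", "x11")
  else
    c("x23", "x24", "x16", "x17", "x3", "x9", "x10", "x11")
}

setMethod("validateNetwork", "NetworkModel", function(model) {
  met <- model@metabolites
  rxn <- model@reactions
  carbon <- stats::setNames(met$carbon_count, met$id)
  # appearance count of balanced metabolites
  counts <- stats::setNames(integer(nrow(met)), met$id)
  for (st in rxn$stoich) {
    nz <- names(st)[st != 0]
    counts[nz] <- counts[nz] + 1L
  }
  orphans <- met$id[met$balanced & counts[met$id] < 2L]
  dup <- c(met$id[duplicated(met$id)], rxn$id[duplicated(rxn$id)])
  missing <- setdiff(.required_aliases(model@condition),
                     rxn$ratio_alias[!is.na(rxn$ratio_alias)])
  imb <- vapply(seq_len(nrow(rxn)), function(j) {
    if (rxn$category[j] %in% c("anabolic", "exchange")) return(0)
    st <- rxn$stoich[[j]]
    sum(st * carbon[names(st)])
  }, numeric(1))
  names(imb) <- rxn$id
  imb <- imb[abs(imb) > 1e-9]
  list(orphans = orphans, duplicates = dup, missing_aliases = missing,
       carbon_imbalance = imb,
       ok = !length(orphans) && !length(dup) && !length(missing) &&
         !length(imb))
})

setMethod("show", "NetworkModel", function(object) {
  met <- object@metabolites
  cat(sprintf("NetworkModel (%s): %d reactions, %d metabolites (%d balanced)\n",
              object@condition, nrow(object@reactions), nrow(met),
              sum(met$balanced)))
  am <- aliasMap(object)
  if (length(am))
    cat("  ratio aliases:",
        paste(sprintf("%s=%s", names(am), am), collapse = ", "), "\n")
})

# ---- JSON serialisation ------------------------------------------------
#
# Stoichiometries are numeric vectors; exact "p/q" coefficients read from a
# file keep their source text in attr(stoich, "rational") (a named character
# vector) so writing the model back emits the identical exact string.

.parse_coeff <- function(v, where) {
  if (is.numeric(v)) return(list(value = v, text = NULL))
  if (is.character(v)) {
    m <- regmatches(v, regexec("^\\s*(-?[0-9]+)\\s*/\\s*([0-9]+)\\s*$", v))[[1]]
    if (length(m) == 3L) {
      q <- as.numeric(m[3])
      if (q == 0) stop("zero denominator in coefficient at ", where)
      return(list(value = as.numeric(m[2]) / q,
                  text = sprintf("%s/%s", m[2], m[3])))
    }
    suppressWarnings(x <- as.numeric(v))
    if (!is.na(x)) return(list(value = x, text = NULL))
  }
  stop("unparseable stoichiometric coefficient at ", where, ": ", v)
}

#' Write a network model to JSON
#'
#' The dialect is
#' `{"condition": ..., "metabolites": [...], "reactions": [...]}` with
#' reaction stoichiometries as `{"met": coeff}` maps; coefficients may be
#' numbers or exact `"p/q"` strings (preserved round-trip).
#'
#' @param model a [NetworkModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  obj <- list(
    condition = model@condition,
    metabolites = lapply(seq_len(nrow(met)), function(i) list(
      id = met$id[i], name = met$name[i], compartment = met$compartment[i],
      balanced = met$balanced[i], carbon_count = met$carbon_count[i])),
    reactions = lapply(seq_len(nrow(rxn)), function(i) {
      st <- rxn$stoich[[i]]
      rational <- attr(st, "rational")
      stoich <- lapply(names(st), function(m) {
        if (!is.null(rational) && m %in% names(rational)) rational[[m]]
        else unname(st[[m]])
      })
      names(stoich) <- names(st)
      out <- list(id = rxn$id[i], name = rxn$name[i], stoich = stoich,
                  reversible = rxn$reversible[i], category = rxn$category[i])
      if (!is.na(rxn$ratio_alias[i])) out$ratio_alias <- rxn$ratio_alias[i]
      out
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network model from JSON
#'
#' @param path file in the dialect written by [writeNetwork()].
#' @return a validated [NetworkModel-class]; `writeNetwork()` then
#'   `readNetwork()` is the identity field for field.
#' @export
readNetwork <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$condition) || !obj$condition %in% .mfa_conditions)
    stop("network file ", path, ": missing or unknown 'condition'")
  met <- do.call(rbind, lapply(obj$metabolites, function(m) {
    for (f in c("id", "compartment", "balanced", "carbon_count"))
      if (is.null(m[[f]]))
        stop("network file ", path, ": metabolite missing key '", f, "'")
    if (!m$compartment %in% .mfa_compartments)
      stop("network file ", path, ": unknown compartment '", m$compartment,
           "' for metabolite '", m$id, "'")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               balanced = isTRUE(m$balanced),
               carbon_count = as.integer(m$carbon_count),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(met$id))
    stop("network file ", path, ": duplicate metabolite id '",
         met$id[duplicated(met$id)][1], "'")
  rlist <- lapply(obj$reactions, function(r) {
    for (f in c("id", "stoich", "reversible", "category"))
      if (is.null(r[[f]]))
        stop("network file ", path, ": reaction missing key '", f, "'")
    if (!r$category %in% .mfa_categories)
      stop("network file ", path, ": unknown category '", r$category,
           "' for reaction '", r$id, "'")
    parsed <- lapply(names(r$stoich), function(m)
      .parse_coeff(r$stoich[[m]],
                   sprintf("reaction '%s', metabolite '%s'", r$id, m)))
    st <- stats::setNames(vapply(parsed, `[[`, numeric(1), "value"),
                          names(r$stoich))
    texts <- lapply(parsed, `[[`, "text")
    has_text <- !vapply(texts, is.null, logical(1))
    if (any(has_text))
      attr(st, "rational") <- stats::setNames(
        unlist(texts[has_text]), names(r$stoich)[has_text])
    .rx(r$id, r$name %||% r$id, st, isTRUE(r$reversible), r$category,
        if (is.null(r$ratio_alias)) NA_character_ else r$ratio_alias)
  })
  ids <- vapply(rlist, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("network file ", path, ": duplicate reaction id '",
         ids[duplicated(ids)][1], "'")
  new("NetworkModel", metabolites = met, reactions = .reactions_df(rlist),
      condition = obj$condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
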