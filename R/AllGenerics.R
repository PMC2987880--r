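#' Stoichiometric matrix of a network model
#'
#' Builds the matrix `S` with one row per *balanced* metabolite and one
#' column per reaction; `S[i, j]` is the signed coefficient of metabolite `i`
#' in reaction `j`. Unbalanced species (CO2, external pools, biomass sinks)
#' produce no rows. All-zero columns indicate disconnected reactions and
#' raise an error.
#'
#' @param model a [NetworkModel-class].
#' @return numeric matrix with metabolite ids as row names and reaction ids
#'   as column names.
#' @examples
#' S <- stoichiometricMatrix(buildNetwork("hypoxic"))
#' dim(S)  # 15 balanced metabolites x 34 reactions
#' @export
setGeneric("stoichiometricMatrix",
           function(model) standardGeneric("stoichiometricMatrix"))

#' Validate a network model
#'
#' Report-only diagnostics: orphan metabolites (balanced species appearing in
#' fewer than two reactions), duplicate ids, ratio aliases required by the
#' condition's constraint set but missing, and per-reaction carbon imbalance
#' computed from metabolite carbon counts (anabolic drains and exchange
#' reactions are exempt; CO2 is counted).
#'
#' @param model a [NetworkModel-class].
#' @return a list with elements `orphans`, `duplicates`, `missing_aliases`,
#'   `carbon_imbalance` (named numeric, mmol C per unit flux) and `ok`
#'   (logical).
#' @export
setGeneric("validateNetwork",
           function(model) standardGeneric("validateNetwork"))

#' Compute METAFoR flux ratios from a flux vector
#'
#' Evaluates the four flux ratios at a given flux distribution, using the
#' reactions carrying the corresponding ratio aliases:
#' `a = x23 / (x23 + x16)`, `b = x23star / (x23star + x16)` (normoxic),
#' `c = x17 / (x17 + x24)`, and
#' `d = (x9 + 2 x11 + 3 x10) / (2 x3 + x9 + x10)`.
#' Values outside \[0, 1\] (possible for `d`, or for `b` when the net
#' transport runs outward) are reported raw with a warning.
#'
#' @param fluxes named flux vector over the model's reactions, or a
#'   [FluxSolution-class].
#' @param model a [NetworkModel-class] carrying the ratio aliases.
#' @return a [RatioSet-class] with `sds` set to `NA` (computed, not
#'   measured) unless supplied.
#' @export
setGeneric("computeRatios",
           function(fluxes, model, ...) standardGeneric("computeRatios"))

#' Translate a ratio set into linear constraint rows
#'
#' Builds the equality submatrix F and the single inequality row of the
#' flux-balancing system from measured METAFoR ratios:
#' `x23 (1-a) - x16 a = 0`, `x23star (1-b) - x16 b = 0`,
#' `x17 (1-c) - x24 c = 0` (each only when its ratio is present), and the
#' pentose-phosphate bound `x9 (1-d) + 2 x11 + x10 (3-d) - 2 x3 <= 0`.
#' Rows are placed at the alias columns and zero elsewhere.
#'
#' @param ratios a [RatioSet-class] valid for the model's condition.
#' @param model a [NetworkModel-class].
#' @return list with `equality_matrix` (rows x reactions), `equality_rhs`
#'   (zeros), `row_names`, `inequality_row` (or `NULL` when `d` is absent),
#'   `inequality_rhs` (0) and `row_weights` (1/sd per equality row).
#' @export
setGeneric("assembleConstraintRows",
           function(ratios, model) standardGeneric("assembleConstraintRows"))

#' Assemble the complete flux-balancing system
#'
#' Stacks the balanced-metabolite mass balances (rhs 0), the measurement rows
#' pinning exchange and drain fluxes to their measured values, and the
#' METAFoR ratio equality rows into one least-squares system, together with
#' the inequality row and the irreversibility lower bounds.
#'
#' @param model a [NetworkModel-class].
#' @param rates a [RateTable-class]; every name must be a reaction id.
#' @param ratios a [RatioSet-class] matching `condition(model)`; may be an
#'   empty ratio set.
#' @param weighting `"whitened"` (rows divided by their measurement sd,
#'   default) or `"unweighted"`.
#' @param strict if `TRUE`, measurement rows are enforced exactly instead of
#'   entering the least-squares objective.
#' @return an [AssembledSystem-class].
#' @export
setGeneric("assembleSystem",
           function(model, rates, ratios,
                    weighting = c("whitened", "unweighted"),
                    strict = FALSE)
             standardGeneric("assembleSystem"))

#' Solve the assembled system for the flux distribution
#'
#' Minimizes the weighted residual norm `|| W (N x - b) ||^2` subject to the
#' irreversibility lower bounds, the pentose-phosphate inequality and the
#' hard metabolite balances, by quadratic programming. The returned solution
#' carries residuals, the active-constraint report and a projected-gradient
#' optimality certificate (tolerance 1e-10).
#'
#' @param system an [AssembledSystem-class].
#' @param on_underdetermined `"error"` (default) to fail on structurally
#'   free flux directions, `"min-norm"` to return the minimum-norm solution
#'   with a warning.
#' @return a [FluxSolution-class].
#' @export
setGeneric("solveFluxes",
           function(system, on_underdetermined = c("error", "min-norm"))
             standardGeneric("solveFluxes"))

#' Branch-point flux fractions
#'
#' Fractional carbon-flux distributions at the three reported branch points:
#' the glucose-6-phosphate split (oxidative PPP vs glycolysis as fractions of
#' glucose uptake), the pyruvate node (pyruvate dehydrogenase vs
#' decarboxylase vs carboxylase), and the TCA cycle (respirative flux from
#' alpha-ketoglutarate vs net anaplerotic input).
#'
#' @param solution a [FluxSolution-class] (or named flux vector).
#' @param model a [NetworkModel-class].
#' @return nested list with elements `g6p`, `pyruvate`, `tca`; nodes with
#'   zero throughput are returned as `NA` with a flag.
#' @export
setGeneric("branchFractions",
           function(solution, model) standardGeneric("branchFractions"))

#' Normalize fluxes to the specific glucose uptake rate
#'
#' @param solution a [FluxSolution-class] or named flux vector.
#' @return named numeric vector; the glucose uptake reaction maps to 1.
#' @export
setGeneric("normalizeFluxes",
           function(solution) standardGeneric("normalizeFluxes"))

#' Sensitivity of the flux estimate to the measured parameters
#'
#' Computes `W` with `W[i, j] = d x_i / d p_j`, the response of estimated
#' flux `i` to measured parameter `j` (the measured rates and the METAFoR
#' equality ratios). The analytic mode differentiates the KKT system of the
#' constrained least-squares estimator on the face of constraints active at
#' the solution; the finite-difference mode re-solves at perturbed
#' parameters (relative step 1e-6) and warns if the active set changes
#' (one-sided differences are then used).
#'
#' @param system an [AssembledSystem-class].
#' @param solution the [FluxSolution-class] for `system`.
#' @param mode `"analytic"` (default) or `"finite_difference"`.
#' @return numeric matrix, fluxes x parameters, with dimnames.
#' @export
setGeneric("sensitivityMatrix",
           function(system, solution, mode = c("analytic", "finite_difference"))
             standardGeneric("sensitivityMatrix"))

#' Condition accessor
#' @param object a PichiaMFA object with an oxygenation condition.
#' @return character scalar.
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' Flux vector accessor
#' @param object a [FluxSolution-class] or [SyntheticDataset-class].
#' @return named numeric vector.
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))
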