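# Quadratic-programming core of the flux estimation.
#
# The estimate minimizes || W (N x - b) ||^2 subject to
#   * hard equalities: metabolite balance rows (structural), plus the
#     measurement rows in strict mode,
#   * the pentose-phosphate inequality row (row . x <= 0),
#   * lower bounds (0 for irreversible reactions).
# Balance rows stay in the objective too (their residual is zero at any
# feasible point, so this is harmless and keeps the quadratic term well
# conditioned). Optimality is certified post hoc by the projected-gradient
# norm with tolerance 1e-10 on the normalized scale.

.kkt_tolerance <- 1e-10

# split the system into objective and hard-equality parts
.system_parts <- function(system) {
  hard <- system@row_type == "balance"
  if (system@strict) hard <- hard | system@row_type == "measurement"
  list(hard = hard,
       E = system@N[hard, , drop = FALSE],
       e = system@b[hard],
       soft = !hard)
}

.solve_qp <- function(system, on_underdetermined = "error") {
  N <- system@N; b <- system@b; w <- system@weights
  p <- ncol(N)
  parts <- .system_parts(system)
  Nw <- N * w
  bw <- b * w
  Dmat <- 2 * crossprod(Nw)
  dvec <- 2 * crossprod(Nw, bw)
  # structural identifiability: free directions not covered by any row or
  # hard equality are reported by reaction id
  M <- rbind(Nw, parts$E)
  qrM <- qr(M)
  ridge <- 0
  if (qrM$rank < p) {
    ns <- .null_basis(M)
    loose <- colnames(N)[apply(abs(ns), 1, max) > 1e-8]
    if (on_underdetermined == "error")
      stop("underdetermined system: free flux direction(s) involving ",
           paste(loose, collapse = ", "))
    warning("rank-deficient system; returning the minimum-norm solution ",
            "(free directions: ", paste(loose, collapse = ", "), ")")
    ridge <- 1e-10 * mean(diag(Dmat))
  } else {
    # solve.QP needs strict positive definiteness; add a ridge at numerical
    # noise level relative to the problem scale
    ridge <- 1e-12 * mean(diag(Dmat))
  }
  Dmat <- Dmat + diag(ridge, p)
  # constraints in solve.QP's A^T x >= b0 convention, equalities first
  Amat <- NULL; bvec <- NULL; meq <- 0L
  if (nrow(parts$E)) {
    Amat <- t(parts$E); bvec <- parts$e; meq <- nrow(parts$E)
  }
  finite_lb <- which(is.finite(system@lower))
  if (length(finite_lb)) {
    B <- matrix(0, p, length(finite_lb))
    B[cbind(finite_lb, seq_along(finite_lb))] <- 1
    Amat <- cbind(Amat, B)
    bvec <- c(bvec, system@lower[finite_lb])
  }
  has_ineq <- length(system@inequality) > 0
  if (has_ineq) {
    Amat <- cbind(Amat, -system@inequality)
    bvec <- c(bvec, -system@inequality_rhs)
  }
  if (is.null(Amat)) {  # fully unconstrained problem
    sol <- list(solution = solve(Dmat, dvec), iact = integer(0))
  } else {
    sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = meq)
  }
  x <- stats::setNames(as.numeric(sol$solution), colnames(N))
  act <- sol$iact[sol$iact > 0]
  act_ineq <- act[act > meq] - meq   # indices into the inequality block
  nb <- length(finite_lb)
  active_bounds <- colnames(N)[finite_lb[act_ineq[act_ineq <= nb]]]
  inequality_active <- has_ineq && any(act_ineq == nb + 1L)
  # polish: with the active set fixed, the solution is an equality-
  # constrained least-squares problem; re-solve it by the null-space/QR
  # method, which is far better conditioned than the QP normal equations
  xp <- .polish_ls(system, Nw, bw, active_bounds, inequality_active)
  if (!is.null(xp)) {
    feas <- all(xp - system@lower >= -1e-9) &&
      (!has_ineq ||
       sum(system@inequality * xp) <= system@inequality_rhs + 1e-9)
    # the face solution is the exact constrained optimum; the raw QP point
    # can undercut its SSR only by sitting slightly off the constraints
    if (feas) x <- stats::setNames(as.numeric(xp), colnames(N))
  }
  list(x = x, Dmat = Dmat, dvec = dvec, ridge = ridge,
       active_bounds = active_bounds, inequality_active = inequality_active,
       parts = parts)
}

# exact solve of min ||Nw x - bw|| s.t. active constraints hold with
# equality, via a null-space parametrization
.polish_ls <- function(system, Nw, bw, active_bounds, inequality_active) {
  A <- .active_matrix(system, active_bounds, inequality_active)
  parts <- .system_parts(system)
  a <- c(parts$e, system@lower[active_bounds],
         if (inequality_active) system@inequality_rhs)
  if (!nrow(A)) {
    qrN <- qr(Nw)
    if (qrN$rank < ncol(Nw)) return(NULL)
    return(qr.coef(qrN, bw))
  }
  xp <- tryCatch(crossprod(A, solve(tcrossprod(A), a)),
                 error = function(e) NULL)
  if (is.null(xp)) return(NULL)
  Z <- .null_basis(A)
  if (!ncol(Z)) return(as.numeric(xp))
  M <- Nw %*% Z
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) return(NULL)
  y <- qr.coef(qrM, bw - Nw %*% xp)
  as.numeric(xp + Z %*% y)
}

.null_basis <- function(M) {
  # orthonormal basis of the null space of M (columns)
  p <- ncol(M)
  qrt <- qr(t(M))
  r <- qrt$rank
  if (r >= p) return(matrix(0, p, 0))
  qr.Q(qrt, complete = TRUE)[, (r + 1):p, drop = FALSE]
}

# rows of the active constraint matrix at a solution (hard equalities,
# active bounds, active inequality)
.active_matrix <- function(system, active_bounds, inequality_active) {
  parts <- .system_parts(system)
  A <- parts$E
  ids <- colnames(system@N)
  if (length(active_bounds)) {
    B <- matrix(0, length(active_bounds), length(ids))
    B[cbind(seq_along(active_bounds), match(active_bounds, ids))] <- 1
    A <- rbind(A, B)
  }
  if (inequality_active) A <- rbind(A, system@inequality)
  A
}

setMethod("solveFluxes", "AssembledSystem",
  function(system, on_underdetermined = c("error", "min-norm")) {
    on_underdetermined <- match.arg(on_underdetermined)
    if (!any(system@row_type == "measurement"))
      stop("system has no measurement rows; fluxes are unidentifiable")
    qp <- .solve_qp(system, on_underdetermined)
    x <- qp$x
    N <- system@N; b <- system@b; w <- system@weights
    resid <- as.numeric(N %*% x - b)
    names(resid) <- system@row_id
    soft <- system@row_type != "balance"
    weighted_ssr <- sum((w[soft] * resid[soft])^2)
    # projected-gradient optimality certificate, evaluated residual-first
    # (numerically stable) and without the factorization ridge
    Nw <- N * w; bw <- b * w
    g <- as.numeric(2 * crossprod(Nw, Nw %*% x - bw))
    A <- .active_matrix(system, qp$active_bounds, qp$inequality_active)
    gp <- if (nrow(A)) {
      P <- .null_basis(A)
      if (ncol(P)) as.numeric(crossprod(P, g)) else numeric(0)
    } else g
    kkt <- if (length(gp)) max(abs(gp)) / max(1, max(abs(qp$dvec))) else 0
    if (kkt > .kkt_tolerance)
      warning(sprintf("projected gradient %.3g exceeds tolerance %.1g",
                      kkt, .kkt_tolerance))
    # residual degrees of freedom: soft rows minus free directions
    nfree <- ncol(N) - qr(A)$rank
    dof <- sum(soft) - nfree
    glc <- .glucose_flux(x, system@model)
    normalized <- if (is.finite(glc) && glc > 0) x / glc
                  else stats::setNames(rep(NA_real_, length(x)), names(x))
    new("FluxSolution", x = x, residuals = resid,
        weighted_ssr = weighted_ssr, dof = dof,
        active_bounds = qp$active_bounds,
        inequality_active = qp$inequality_active,
        normalized = normalized, kkt_residual = kkt, system = system)
  })

.glucose_flux <- function(x, model) {
  if ("glc_upt" %in% names(x)) unname(x[["glc_upt"]]) else NA_real_
}

setMethod("fluxes", "FluxSolution", function(object) object@x)

#' @describeIn FluxSolution-class per-row residuals (unweighted scale).
#' @param object a [FluxSolution-class].
#' @export
fluxResiduals <- function(object) object@residuals

#' @describeIn FluxSolution-class fluxes normalized to glucose uptake.
#' @export
normalizedFluxes <- function(object) object@normalized

setMethod("show", "FluxSolution", function(object) {
  cat(sprintf(paste0("FluxSolution: %d fluxes, weighted SSR %.4g, ",
                     "dof %d, projected gradient %.2g\n"),
              length(object@x), object@weighted_ssr, object@dof,
              object@kkt_residual))
  if (length(object@active_bounds))
    cat("  active lower bounds:",
        paste(object@active_bounds, collapse = ", "), "\n")
  if (object@inequality_active)
    cat("  pentose-phosphate inequality active\n")
  print(utils::head(round(data.frame(flux = object@x,
                                     normalized = object@normalized), 4), 8))
  if (length(object@x) > 8) cat("  ...\n")
})

setMethod("normalizeFluxes", "FluxSolution", function(solution) {
  glc <- .glucose_flux(solution@x, solution@system@model)
  if (!is.finite(glc) || glc <= 0)
    stop("glucose uptake flux is zero or missing; cannot normalize")
  solution@x / glc
})

setMethod("normalizeFluxes", "numeric", function(solution) {
  if (!"glc_upt" %in% names(solution))
    stop("flux vector has no glucose uptake ('glc_upt') entry")
  glc <- solution[["glc_upt"]]
  if (!is.finite(glc) || glc <= 0)
    stop("glucose uptake flux is zero or missing; cannot normalize")
  solution / glc
})

.branch_from_vector <- function(x, model) {
  cond <- condition(model)
  get <- function(id) if (id %in% names(x)) unname(x[[id]]) else 0
  # G6P split: oxidative PPP vs glycolysis as fractions of glucose uptake
  glc <- get("glc_upt")
  g6p <- if (glc > 0) list(ppp = get("zwf") / glc, glycolysis = get("pgi") / glc)
         else { warning("zero G6P throughput"); list(ppp = NA, glycolysis = NA) }
  # pyruvate node: PDH vs PDC vs pyruvate carboxylase
  tot <- get("pdh") + get("pdc") + get("pyc")
  pyr <- if (tot > 0)
    list(pdh = get("pdh") / tot, pdc = get("pdc") / tot, pyc = get("pyc") / tot)
  else { warning("zero pyruvate-node throughput"); list(pdh = NA, pdc = NA, pyc = NA) }
  # TCA: respirative (AKG -> Oaa_mit span) vs net anaplerotic input
  resp <- get("tca_mdh")
  ana_in <- if (cond == "normoxic") max(get("oaa_net"), 0)
            else max(get("oaa_in") - get("oaa_out"), 0)
  den <- resp + ana_in
  tca <- if (den > 0) list(respirative = resp / den, anaplerotic = ana_in / den)
         else { warning("zero TCA throughput"); list(respirative = NA, anaplerotic = NA) }
  list(g6p = g6p, pyruvate = pyr, tca = tca)
}

setMethod("branchFractions", signature(solution = "FluxSolution",
                                       model = "NetworkModel"),
  function(solution, model) .branch_from_vector(solution@x, model))

setMethod("branchFractions", signature(solution = "numeric",
                                       model = "NetworkModel"),
  function(solution, model) .branch_from_vector(solution, model))
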