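# Flux uncertainty through the Fisher Information Matrix.
#
# The measured parameters p are the exchange/drain rates (entering the
# right-hand side) and the METAFoR equality ratios (entering the constraint
# row coefficients). The constrained least-squares estimate x(p) is
# differentiated on the face of constraints active at the solution; the flux
# covariance is W C W^T with C the diagonal measurement variance matrix, and
# the information matrix is its (pseudo-)inverse. On unconstrained full-rank
# systems this coincides exactly with the classical FIM = N^T C^-1 N of
# weighted least squares.

# measured parameters of a system: rates then equality ratios
.system_parameters <- function(system) {
  mi <- which(system@row_type == "measurement")
  ri <- which(system@row_type == "ratio")
  lab <- function(prefix, idx)   # paste0 maps zero-length to "", guard it
    if (length(idx)) paste0(prefix, system@row_id[idx]) else character(0)
  data.frame(
    name = c(lab("rate:", mi), lab("ratio:", ri)),
    kind = c(rep("rate", length(mi)), rep("ratio", length(ri))),
    row = c(mi, ri),
    id = c(system@row_id[mi], system@row_id[ri]),
    value = c(system@b[mi], system@ratios@ratios[system@row_id[ri]]),
    sd = system@row_sd[c(mi, ri)],
    stringsAsFactors = FALSE)
}

# derivative of a ratio equality row with respect to its ratio value:
# row(r) has (1-r) at the numerator alias and -r at the denominator alias,
# so d row / d r is -1 at both columns
.ratio_row_derivative <- function(system, ratio_name) {
  model <- system@model
  am <- aliasMap(model)
  pair <- switch(ratio_name,
                 a = c("x23", "x16"), b = c("x23star", "x16"),
                 c = c("x17", "x24"),
                 stop("no equality row for ratio '", ratio_name, "'"))
  drow <- stats::setNames(numeric(ncol(system@N)), colnames(system@N))
  drow[am[pair]] <- -1
  drow
}

# Differentiates the face least-squares estimator x(p) = xp(p) + Z y(p),
# where A x = a is the active-constraint set, Z spans null(A), and
# y = argmin || M y - r0 ||, M = Nw Z, r0 = bw - Nw xp. This null-space
# form is stable across the weight scales that arise from whitening (the
# balance rows drop out of M because Z already satisfies them).
.analytic_sensitivity <- function(system, solution) {
  pars <- .system_parameters(system)
  N <- system@N; b <- system@b; w <- system@weights
  p <- ncol(N)
  Nw <- N * w; bw <- b * w
  A <- .active_matrix(system, solution@active_bounds,
                      solution@inequality_active)
  parts <- .system_parts(system)
  if (nrow(A)) {
    AAt <- tcrossprod(A)
    xp <- as.numeric(crossprod(A, solve(AAt, c(
      parts$e, system@lower[solution@active_bounds],
      if (solution@inequality_active) system@inequality_rhs))))
    Z <- .null_basis(A)
  } else {
    xp <- numeric(p)
    Z <- diag(p)
  }
  W <- matrix(0, p, nrow(pars), dimnames = list(colnames(N), pars$name))
  if (!ncol(Z)) return(W)  # fully pinned by constraints
  M <- Nw %*% Z
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stop("rank-deficient reduced system; sensitivities undefined")
  r0 <- bw - as.numeric(Nw %*% xp)
  y <- qr.coef(qrM, r0)
  res <- r0 - as.numeric(M %*% y)
  R <- qr.R(qrM)
  xhat <- xp + as.numeric(Z %*% y)
  hard_rows <- which(parts$hard)
  for (j in seq_len(nrow(pars))) {
    k <- pars$row[j]
    if (pars$kind[j] == "rate") {
      dbw <- numeric(nrow(N)); dbw[k] <- w[k]
      dxp <- numeric(p)
      if (system@strict) {
        pos <- match(k, hard_rows)  # the row is also a hard equality
        de <- numeric(nrow(A)); de[pos] <- 1
        dxp <- as.numeric(crossprod(A, solve(AAt, de)))
      }
      dr0 <- dbw - as.numeric(Nw %*% dxp)
      dy <- qr.coef(qrM, dr0)
      W[, j] <- dxp + as.numeric(Z %*% dy)
    } else {
      drow <- .ratio_row_derivative(system, pars$id[j])
      # dM = w_k e_k (drow^T Z), dr0_k = -w_k (drow . xp)
      v1 <- w[k] * res[k] * as.numeric(crossprod(Z, drow))
      piv <- qrM$pivot
      dy1 <- numeric(ncol(M))
      dy1[piv] <- backsolve(R, backsolve(R, v1[piv], transpose = TRUE))
      dr <- numeric(nrow(N)); dr[k] <- -w[k] * sum(drow * xhat)
      dy2 <- qr.coef(qrM, dr)
      W[, j] <- as.numeric(Z %*% (dy1 + dy2))
    }
  }
  W
}

.fd_sensitivity <- function(system, solution, step = 1e-6) {
  pars <- .system_parameters(system)
  p <- ncol(system@N)
  W <- matrix(0, p, nrow(pars),
              dimnames = list(colnames(system@N), pars$name))
  act0 <- list(solution@active_bounds, solution@inequality_active)
  resolve <- function(sys) suppressWarnings(solveFluxes(sys))
  for (j in seq_len(nrow(pars))) {
    h <- max(abs(pars$value[j]), 1e-3) * step
    up <- .perturb_parameter(system, pars[j, ], +h)
    dn <- .perturb_parameter(system, pars[j, ], -h)
    s_up <- resolve(up); s_dn <- resolve(dn)
    same <- function(s) identical(s@active_bounds, act0[[1]]) &&
      identical(s@inequality_active, act0[[2]])
    if (same(s_up) && same(s_dn)) {
      W[, j] <- (s_up@x - s_dn@x) / (2 * h)
    } else if (same(s_up)) {
      warning("active set changed under perturbation of ", pars$name[j],
              "; one-sided difference used")
      W[, j] <- (s_up@x - solution@x) / h
    } else {
      warning("active set changed under perturbation of ", pars$name[j],
              "; one-sided difference used")
      W[, j] <- (solution@x - s_dn@x) / h
    }
  }
  W
}

# a copy of the system with one measured parameter shifted by delta
.perturb_parameter <- function(system, par, delta) {
  if (par$kind == "rate") {
    system@b[par$row] <- system@b[par$row] + delta
  } else {
    r <- system@ratios@ratios[[par$id]] + delta
    system@ratios@ratios[[par$id]] <- r
    drow <- .ratio_row_derivative(system, par$id)
    system@N[par$row, ] <- system@N[par$row, ] + delta * drow
  }
  system
}

setMethod("sensitivityMatrix",
  signature(system = "AssembledSystem", solution = "FluxSolution"),
  function(system, solution, mode = c("analytic", "finite_difference")) {
    mode <- match.arg(mode)
    if (mode == "analytic") .analytic_sensitivity(system, solution)
    else .fd_sensitivity(system, solution)
  })

#' Fisher Information Matrix from sensitivities
#'
#' `FIM = sum_k W_k^T C_k^-1 W_k` over independent measurement blocks; with
#' a single block this is `W^T C^-1 W`, where `W` maps the estimated
#' parameters to the measured quantities and `C` is the (diagonal)
#' measurement variance-covariance matrix.
#'
#' @param W sensitivity matrix (measurements x parameters), or a list of
#'   such matrices for independent blocks.
#' @param C variance-covariance matrix (or list, matching `W`); diagonal
#'   matrices may be given as vectors of variances.
#' @return the information matrix (symmetric positive semidefinite).
#' @examples
#' fisherInformation(diag(3), diag(3))  # identity
#' @export
fisherInformation <- function(W, C) {
  if (!is.list(W)) { W <- list(W); C <- list(C) }
  if (length(W) != length(C))
    stop("W and C block lists must have equal length")
  acc <- NULL
  for (k in seq_along(W)) {
    Wk <- as.matrix(W[[k]])
    Ck <- C[[k]]
    if (is.vector(Ck)) Ck <- diag(Ck, nrow = length(Ck))
    if (nrow(Ck) != nrow(Wk))
      stop("C block ", k, " does not conform to W")
    ev <- eigen(Ck, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("C must be positive definite")
    term <- crossprod(Wk, solve(Ck, Wk))
    acc <- if (is.null(acc)) term else acc + term
  }
  (acc + t(acc)) / 2
}

#' Per-parameter standard deviations from an information matrix
#'
#' `sigma_j = sqrt((FIM^-1)_jj)`. A singular information matrix is inverted
#' by Moore-Penrose pseudo-inverse with a rank warning (unidentifiable
#' directions get the pseudo-variance of the identifiable subspace).
#'
#' @param FIM information matrix.
#' @return named numeric vector of standard deviations.
#' @export
fluxSd <- function(FIM) {
  FIM <- (FIM + t(FIM)) / 2
  r <- qr(FIM)$rank
  inv <- if (r < nrow(FIM)) {
    warning("singular information matrix (rank ", r, " of ", nrow(FIM),
            "); pseudo-inverse used")
    MASS::ginv(FIM)
  } else solve(FIM)
  s <- sqrt(pmax(diag(inv), 0))
  names(s) <- rownames(FIM)
  s
}

#' Student-t confidence intervals for estimated fluxes
#'
#' `estimate +- sigma * t(alpha/2, v)` per flux; `v = Inf` uses the normal
#' quantile.
#'
#' @param solution a [FluxSolution-class] or named estimate vector.
#' @param sigma named per-flux standard deviations.
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param v degrees of freedom, `>= 1` or `Inf`.
#' @return `data.frame` with `flux_id`, `estimate`, `sigma`, `ci_low`,
#'   `ci_high`.
#' @export
confidenceIntervals <- function(solution, sigma, alpha = 0.05, v = Inf) {
  if (is(solution, "FluxSolution")) solution <- solution@x
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!(is.infinite(v) || v >= 1)) stop("v must be >= 1 (or Inf)")
  tq <- if (is.infinite(v)) stats::qnorm(1 - alpha / 2)
        else stats::qt(1 - alpha / 2, df = v)
  sigma <- sigma[names(solution)]
  data.frame(flux_id = names(solution), estimate = unname(solution),
             sigma = unname(sigma),
             ci_low = unname(solution - sigma * tq),
             ci_high = unname(solution + sigma * tq),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full flux uncertainty report
#'
#' Computes the estimator sensitivity W = dx/dp to the measured rates and
#' ratios, the flux covariance `W C W^T`, Fisher information (its
#' pseudo-inverse), per-flux standard deviations and confidence intervals.
#' Fluxes sitting on an active bound are flagged: the linearization is
#' one-sided there and the reported sigma describes the active face.
#'
#' @param system an [AssembledSystem-class].
#' @param solution its [FluxSolution-class].
#' @param alpha significance level (default 0.05).
#' @param v degrees of freedom for the t quantile; default `NULL` uses the
#'   solution's residual dof when at least 2, otherwise the normal
#'   quantile.
#' @param mode sensitivity mode, see [sensitivityMatrix()].
#' @return an [UncertaintyReport-class].
#' @export
fluxUncertainty <- function(system, solution, alpha = 0.05, v = NULL,
                            mode = "analytic") {
  W <- sensitivityMatrix(system, solution, mode = mode)
  pars <- .system_parameters(system)
  C <- diag(pars$sd^2, nrow = nrow(pars))
  dimnames(C) <- list(pars$name, pars$name)
  if (any(!is.finite(pars$sd) | pars$sd <= 0))
    stop("every measured parameter needs a finite positive sd")
  covx <- W %*% C %*% t(W)
  covx <- (covx + t(covx)) / 2
  sigma <- stats::setNames(sqrt(pmax(diag(covx), 0)), rownames(W))
  FIM <- MASS::ginv(covx)
  FIM <- (FIM + t(FIM)) / 2
  if (is.null(v)) v <- if (solution@dof >= 2) solution@dof else Inf
  ci <- confidenceIntervals(solution, sigma, alpha = alpha, v = v)
  flags <- stats::setNames(rep("", length(sigma)), names(sigma))
  flags[solution@active_bounds] <- "active_bound"
  if (solution@inequality_active) {
    ineq_rx <- names(which(system@inequality != 0))
    flags[ineq_rx] <- trimws(paste(flags[ineq_rx], "active_inequality"))
  }
  ci$flag <- unname(flags[ci$flux_id])
  # slot "C" cannot be passed by name through new(): it would partial-match
  # the Class argument; assign it afterwards
  rep <- new("UncertaintyReport", W = W, FIM = FIM, covariance = covx,
             sigma = sigma, ci = ci, alpha = alpha, v = as.numeric(v),
             flags = flags)
  rep@C <- C
  rep
}

setMethod("show", "UncertaintyReport", function(object) {
  cat(sprintf("UncertaintyReport: %d fluxes, %d parameters, alpha = %.3g, v = %s\n",
              nrow(object@W), ncol(object@W), object@alpha,
              if (is.infinite(object@v)) "Inf (normal)" else object@v))
  print(utils::head(object@ci, 8))
  if (nrow(object@ci) > 8) cat("  ...\n")
})

#' Monte-Carlo validation of the FIM uncertainty
#'
#' Re-solves the system `n_reps` times with measurements resampled from
#' their stated noise (Gaussian rates; Gaussian ratios truncated to
#' \[0, 1\]) and compares the empirical per-flux standard deviations to the
#' FIM-based sigma.
#'
#' @param system an [AssembledSystem-class].
#' @param n_reps number of replicates (`>= 2`).
#' @param seed integer seed.
#' @param noise_model `"stated"` resamples each measured parameter from its
#'   own sd (default).
#' @return `data.frame` with `flux_id`, `empirical_sd` (all replicates),
#'   `empirical_sd_inactive` (replicates whose bound/inequality set stays
#'   inactive, i.e. the regime where the FIM linearization applies),
#'   `fim_sd`, `ratio` and `ratio_inactive`; the fraction of
#'   constraint-free replicates is attached as attribute
#'   `"frac_inactive"`.
#' @export
monteCarloCheck <- function(system, n_reps = 200, seed = 1,
                            noise_model = "stated") {
  stopifnot(n_reps >= 2)
  base_sol <- solveFluxes(system)
  rep_fim <- fluxUncertainty(system, base_sol)
  pars <- .system_parameters(system)
  set.seed(as.integer(seed))
  X <- matrix(NA_real_, n_reps, ncol(system@N),
              dimnames = list(NULL, colnames(system@N)))
  inactive <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    sys_r <- system
    for (j in seq_len(nrow(pars))) {
      delta <- stats::rnorm(1, 0, pars$sd[j])
      if (pars$kind[j] == "ratio") {
        # keep the resampled ratio inside [0, 1]
        v0 <- pars$value[j]
        delta <- max(min(v0 + delta, 1), 0) - v0
      }
      sys_r <- .perturb_parameter(sys_r, pars[j, ], delta)
    }
    sol_r <- suppressWarnings(solveFluxes(sys_r))
    X[r, ] <- sol_r@x
    inactive[r] <- !length(sol_r@active_bounds) && !sol_r@inequality_active
  }
  emp <- apply(X, 2, stats::sd)
  emp_in <- if (sum(inactive) >= 2)
    apply(X[inactive, , drop = FALSE], 2, stats::sd) else emp * NA_real_
  out <- data.frame(flux_id = colnames(X), empirical_sd = unname(emp),
                    empirical_sd_inactive = unname(emp_in),
                    fim_sd = unname(rep_fim@sigma[colnames(X)]),
                    ratio = unname(emp / rep_fim@sigma[colnames(X)]),
                    ratio_inactive =
                      unname(emp_in / rep_fim@sigma[colnames(X)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "frac_inactive") <- mean(inactive)
  out
}
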