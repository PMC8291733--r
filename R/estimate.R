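#' Closed-form (unpenalized) generalized score matching estimate
#'
#' When every block of \eqn{\Gamma} (amplified or not) is invertible, the
#' minimizer of the quadratic loss is unique and available per column:
#' \eqn{\psi_j = \Gamma_j^{-1} g_j}. K is then symmetrized by averaging.
#'
#' @param system An `sm_system`.
#' @param symmetrize Average K with its transpose (default) or keep the raw
#'   column-decoupled solution.
#' @return An `sm_fit` object (see [solve_regularized()]) with
#'   `lambda_K = 0`; the raw per-column solution is kept in `$psi`.
#' @export
closed_form <- function(system, symmetrize = TRUE) {
  stopifnot(inherits(system, "sm_system"))
  m <- system$m
  side <- dim(system$blocks)[1]
  psi <- matrix(0, side, m)
  for (j in seq_len(m)) {
    Gj <- system$blocks[, , j]
    diag(Gj)[seq_len(m)] <- diag(Gj)[seq_len(m)] + system$amplifier[, j]
    sol <- tryCatch(solve(Gj, system$g[, j]), error = function(e) NULL)
    if (is.null(sol))
      abort(sprintf(
        "block %d of Gamma is singular (rank < %d); the unpenalized problem has no unique solution -- amplify() the system (condition C1 fails, e.g. n too small)",
        j, side))
    psi[, j] <- sol
  }
  K <- psi[seq_len(m), , drop = FALSE]
  if (symmetrize) K <- (K + t(K)) / 2
  eta <- if (side > m) psi[m + 1L, ] else NULL
  new_sm_fit(K, eta, system, lambda_K = 0, lambda_eta = 0,
             penalize_diag = FALSE, iterations = 0L, converged = TRUE,
             psi = psi)
}

new_sm_fit <- function(K, eta, system, lambda_K, lambda_eta, penalize_diag,
                       iterations, converged, objective = NULL,
                       objective_trace = NULL, psi = NULL,
                       profiled = FALSE) {
  m <- nrow(K)
  dimnames(K) <- list(system$var_names, system$var_names)
  if (is.null(objective))
    objective <- sm_objective(system, K, eta,
                              lambda_K = lambda_K,
                              lambda_eta = if (profiled) 0 else lambda_eta,
                              penalize_diag = penalize_diag)
  structure(list(
    K = K, eta = eta, lambda_K = lambda_K,
    lambda_eta = if (profiled) "profiled" else lambda_eta,
    penalize_diag = penalize_diag, iterations = iterations,
    converged = converged, objective = objective,
    objective_trace = objective_trace, psi = psi,
    support = support_pairs(K), var_names = system$var_names,
    spec = system$spec, n = system$n, m = m), class = "sm_fit")
}

# off-diagonal support as ordered index pairs (both (i,j) and (j,i))
support_pairs <- function(K, tol = 0) {
  idx <- which(abs(K) > tol & row(K) != col(K), arr.ind = TRUE)
  unname(idx)
}

#' @export
print.sm_fit <- function(x, ...) {
  ne <- sum(x$K[upper.tri(x$K)] != 0)
  cat(sprintf(
    "<sm_fit> m = %d, lambda_K = %.4g, lambda_eta = %s, %d edge%s, %s\n",
    x$m, x$lambda_K,
    if (identical(x$lambda_eta, "profiled")) "profiled"
    else sprintf("%.4g", x$lambda_eta),
    ne, if (ne == 1) "" else "s",
    if (x$converged) sprintf("converged in %d sweeps", x$iterations)
    else sprintf("NOT converged after %d sweeps", x$iterations)))
  invisible(x)
}

#' Evaluate the (regularized, amplified) loss at given parameters
#'
#' @param system An `sm_system`.
#' @param K Interaction matrix; `eta` linear parameter (non-centered).
#' @param lambda_K,lambda_eta Penalty levels.
#' @param penalize_diag Whether the K-diagonal is penalized.
#' @return Scalar objective value.
#' @export
sm_objective <- function(system, K, eta = NULL, lambda_K = 0, lambda_eta = 0,
                         penalize_diag = TRUE) {
  centered <- dim(system$blocks)[1] == system$m
  if (centered) eta <- numeric(0)
  else if (is.null(eta)) abort("eta required for a non-centered system.")
  sm_objective_cpp(system$blocks, system$g, system$amplifier, lambda_K,
                   lambda_eta, penalize_diag, centered, unname(K),
                   as.numeric(eta))
}

#' l1-regularized estimation by symmetric coordinate descent
#'
#' Minimizes the amplified regularized loss
#' \deqn{\tfrac12 \theta^\top \Gamma_\gamma \theta - g^\top \theta
#'       + \lambda_K \|vec(K)\|_1 + \lambda_\eta \|\eta\|_1}
#' over symmetric K (and \eqn{\eta} in the non-centered case) by cyclic
#' coordinate descent: each off-diagonal pair \eqn{(\kappa_{jk},
#' \kappa_{kj})} is updated jointly via the exact soft-threshold step for
#' the combined quadratic coefficient from blocks j and k, so symmetry is
#' maintained throughout. With a strictly positive amplifier the problem is
#' strongly convex and the minimizer unique; without amplification the loss
#' can be unbounded below when n <= m (see [kernel_escape_direction()]).
#'
#' @param system An `sm_system`, normally amplified (see [amplify()]).
#' @param lambda_K Non-negative l1 penalty on K. By default every entry of K
#'   including the diagonal is penalized; set `penalize_diag = FALSE` to
#'   exempt the diagonal.
#' @param lambda_eta Non-negative l1 penalty on eta (0 = unpenalized).
#' @param penalize_diag Penalize the diagonal of K.
#' @param tol Convergence tolerance on the maximum absolute parameter change
#'   per sweep.
#' @param max_iter Maximum number of full sweeps.
#' @param init Optional `sm_fit` or list with `K` (and `eta`) used as a warm
#'   start.
#' @param symmetric Set `FALSE` for the column-decoupled asymmetric solver
#'   (testing only).
#' @return An `sm_fit`: `K` (symmetric), `eta` (or `NULL`), penalty levels,
#'   `iterations`, `converged`, `objective`, `objective_trace` (one value
#'   per sweep), and the off-diagonal `support`.
#' @export
solve_regularized <- function(system, lambda_K, lambda_eta = 0,
                              penalize_diag = TRUE, tol = 1e-8,
                              max_iter = 1000L, init = NULL,
                              symmetric = TRUE) {
  stopifnot(inherits(system, "sm_system"), lambda_K >= 0, lambda_eta >= 0)
  m <- system$m
  centered <- dim(system$blocks)[1] == m
  K0 <- matrix(0, m, m); eta0 <- numeric(if (centered) m else m)
  if (!is.null(init)) {
    K0 <- unname(init$K)
    if (!centered && !is.null(init$eta)) eta0 <- init$eta
  }
  res <- cd_solve_cpp(system$blocks, system$g, system$amplifier, lambda_K,
                      lambda_eta, penalize_diag, centered, K0, eta0, tol,
                      as.integer(max_iter), symmetric)
  if (!res$converged)
    warn(sprintf("coordinate descent did not converge in %d sweeps", max_iter))
  new_sm_fit(res$K, if (centered) NULL else as.numeric(res$eta), system,
             lambda_K = lambda_K, lambda_eta = lambda_eta,
             penalize_diag = penalize_diag, iterations = res$iterations,
             converged = res$converged,
             objective_trace = as.numeric(res$objective_trace))
}

#' Profiled estimation: eta eliminated by Schur complement
#'
#' In the non-centered case with no penalty on \eqn{\eta}, \eqn{\eta} can be
#' profiled out analytically. K then minimizes the centered-like loss with
#' per-block Schur complements
#' \eqn{\Gamma_{\gamma,11.2,j} = \Gamma_{\gamma,11,j} -
#' \Gamma_{12,j}\Gamma_{22,j}^{-1}\Gamma_{12,j}^\top} and linear term
#' \eqn{g_{1,j} - \Gamma_{12,j}\Gamma_{22,j}^{-1} g_{2,j}}, and
#' \eqn{\hat\eta_j = \Gamma_{22,j}^{-1}(g_{2,j} -
#' \Gamma_{12,j}^\top vec(\hat K)_j)} is recovered by back-substitution.
#' Equals [solve_regularized()] with `lambda_eta = 0` up to the solver
#' tolerance.
#'
#' @inheritParams solve_regularized
#' @return An `sm_fit` with `lambda_eta = "profiled"`.
#' @export
solve_profiled <- function(system, lambda_K, penalize_diag = TRUE,
                           tol = 1e-8, max_iter = 1000L, init = NULL) {
  stopifnot(inherits(system, "sm_system"))
  m <- system$m
  if (dim(system$blocks)[1] == m)
    abort("profiling requires a non-centered system (no eta block present).")
  ps <- profiled_system(system)
  fit <- solve_regularized(ps$sys, lambda_K = lambda_K,
                           penalize_diag = penalize_diag, tol = tol,
                           max_iter = max_iter, init = init)
  eta <- vapply(seq_len(m), function(j)
    (system$g[m + 1L, j] -
       sum(ps$G12[, j] * fit$K[, j])) / ps$G22[j], numeric(1))
  new_sm_fit(fit$K, eta, system, lambda_K = lambda_K, lambda_eta = 0,
             penalize_diag = penalize_diag, iterations = fit$iterations,
             converged = fit$converged,
             objective_trace = fit$objective_trace, profiled = TRUE)
}

# Schur-complemented centered system (amplifier folded in) + the pieces
# needed to back-substitute eta
profiled_system <- function(system) {
  m <- system$m
  G22 <- vapply(seq_len(m), function(j) system$blocks[m + 1L, m + 1L, j],
                numeric(1))
  if (any(G22 <= 0))
    abort(sprintf("Gamma_22 is zero in block(s) %s; cannot profile",
                  paste(which(G22 <= 0), collapse = ", ")))
  G12 <- vapply(seq_len(m), function(j) system$blocks[seq_len(m), m + 1L, j],
                numeric(m))
  G12 <- matrix(G12, m, m)
  blocks <- array(0, dim = c(m, m, m))
  g <- matrix(0, m, m)
  for (j in seq_len(m)) {
    B <- system$blocks[seq_len(m), seq_len(m), j]
    diag(B) <- diag(B) + system$amplifier[, j]
    blocks[, , j] <- B - tcrossprod(G12[, j]) / G22[j]
    g[, j] <- system$g[seq_len(m), j] - G12[, j] * system$g[m + 1L, j] / G22[j]
  }
  spec <- system$spec
  spec$centered <- TRUE
  sys <- new_sm_system(blocks, g, spec = spec, h = system$h, n = system$n,
                       column_scales = system$column_scales,
                       var_names = system$var_names)
  list(sys = sys, G12 = G12, G22 = G22)
}

#' Fit a decreasing lambda path with warm starts
#'
#' The grid is log-spaced from \eqn{\lambda_{max}} (the smallest lambda
#' giving an empty off-diagonal support, located by bisection) down to
#' \eqn{\lambda_{max} \cdot} `lambda_min_ratio`; each fit is warm-started
#' from the previous one. Optionally a final `lambda = 0` entry (the
#' amplified closed-form/fully dense end) is appended so ROC curves reach
#' FPR = 1.
#'
#' @inheritParams solve_regularized
#' @param n_lambda Number of grid points (>= 2).
#' @param lambda_min_ratio Ratio of the smallest positive lambda to
#'   \eqn{\lambda_{max}}.
#' @param lambda_eta_rule `"fixed"` (use `lambda_eta` as given, 0 =
#'   unpenalized), `"profiled"` (eliminate eta per [solve_profiled()]), or
#'   `"proportional"` (lambda_eta = `eta_ratio` * lambda_K).
#' @param lambda_eta,eta_ratio See `lambda_eta_rule`.
#' @param include_zero Append a lambda = 0 fit.
#' @return An `sm_path`: list with `lambdas`, `fits` (list of `sm_fit`),
#'   `edge_counts`, and `ebic` (filled by [ebic_select()]).
#' @export
fit_path <- function(system, n_lambda = 50L, lambda_min_ratio = 1e-4,
                     lambda_eta_rule = c("fixed", "profiled", "proportional"),
                     lambda_eta = 0, eta_ratio = 1, penalize_diag = TRUE,
                     tol = 1e-8, max_iter = 1000L, include_zero = FALSE) {
  stopifnot(inherits(system, "sm_system"))
  if (n_lambda < 2) abort("n_lambda must be at least 2.")
  if (lambda_min_ratio <= 0 || lambda_min_ratio > 1)
    abort("lambda_min_ratio must be in (0, 1].")
  lambda_eta_rule <- match.arg(lambda_eta_rule)
  centered <- dim(system$blocks)[1] == system$m
  if (lambda_eta_rule == "profiled" && centered)
    abort("profiled rule needs a non-centered system.")
  one_fit <- function(lam, init) {
    switch(lambda_eta_rule,
      fixed = solve_regularized(system, lam, lambda_eta = lambda_eta,
                                penalize_diag = penalize_diag, tol = tol,
                                max_iter = max_iter, init = init),
      proportional = solve_regularized(system, lam,
                                       lambda_eta = eta_ratio * lam,
                                       penalize_diag = penalize_diag,
                                       tol = tol, max_iter = max_iter,
                                       init = init),
      profiled = solve_profiled(system, lam, penalize_diag = penalize_diag,
                                tol = tol, max_iter = max_iter, init = init))
  }
  empty_support <- function(lam)
    nrow(support_pairs(one_fit(lam, NULL)$K)) == 0
  # bracket and bisect lambda_max (smallest lambda with empty support)
  hi <- max(abs(system$g)) + 1
  while (!empty_support(hi)) hi <- hi * 2
  lo <- hi / 2
  while (empty_support(lo) && lo > 1e-12) lo <- lo / 2
  for (i in 1:40) {
    if ((hi - lo) / hi < 1e-4) break
    mid <- (hi + lo) / 2
    if (empty_support(mid)) hi <- mid else lo <- mid
  }
  lambda_max <- hi
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambda))
  if (lambda_min_ratio == 1) lambdas <- rep(lambda_max, n_lambda)
  fits <- vector("list", length(lambdas))
  init <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- one_fit(lambdas[i], init)
    init <- fits[[i]]
  }
  if (include_zero) {
    if (lambda_eta_rule == "profiled") {
      ps <- profiled_system(system)
      f0 <- closed_form(ps$sys)
      m <- system$m
      eta <- vapply(seq_len(m), function(j)
        (system$g[m + 1L, j] - sum(ps$G12[, j] * f0$K[, j])) / ps$G22[j],
        numeric(1))
      f0 <- new_sm_fit(f0$K, eta, system, lambda_K = 0, lambda_eta = 0,
                       penalize_diag = penalize_diag, iterations = 0L,
                       converged = TRUE, profiled = TRUE)
    } else {
      f0 <- closed_form(system)
    }
    fits <- c(fits, list(f0))
    lambdas <- c(lambdas, 0)
  }
  structure(list(
    lambdas = lambdas, fits = fits,
    edge_counts = vapply(fits, function(f) nrow(f$support) %/% 2L,
                         integer(1)),
    ebic = rep(NA_real_, length(fits)), lambda_max = lambda_max),
    class = "sm_path")
}

#' @export
print.sm_path <- function(x, ...) {
  cat(sprintf("<sm_path> %d lambda values in [%.4g, %.4g], edges %d..%d\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              min(x$edge_counts), max(x$edge_counts)))
  invisible(x)
}

#' KKT residuals of a fitted model
#'
#' For each penalized coordinate the subgradient optimality condition is
#' checked on the amplified loss: at a nonzero coordinate
#' \eqn{\partial loss + \lambda\, sign = 0}; at a zero coordinate
#' \eqn{|\partial loss| \le \lambda}. Returns the worst violation.
#'
#' @param system The `sm_system` the fit came from.
#' @param fit An `sm_fit` from [solve_regularized()].
#' @return Max absolute KKT violation (scalar).
#' @export
kkt_violation <- function(system, fit) {
  m <- system$m
  centered <- dim(system$blocks)[1] == m
  K <- unname(fit$K)
  eta <- if (centered) NULL else fit$eta
  grad <- matrix(0, dim(system$blocks)[1], m) # d loss / d theta per block
  for (j in seq_len(m)) {
    Gj <- system$blocks[, , j]
    diag(Gj)[seq_len(m)] <- diag(Gj)[seq_len(m)] + system$amplifier[, j]
    th <- if (centered) K[, j] else c(K[, j], eta[j])
    grad[, j] <- Gj %*% th - system$g[, j]
  }
  worst <- 0
  lam <- fit$lambda_K
  for (j in seq_len(m)) for (k in j:m) {
    if (j == k) {
      gd <- grad[j, j]
      pen <- if (fit$penalize_diag) lam else 0
      v <- if (K[j, j] != 0) abs(gd + pen * sign(K[j, j]))
           else max(0, abs(gd) - pen)
    } else {
      gd <- grad[k, j] + grad[j, k] # paired coordinate
      v <- if (K[k, j] != 0) abs(gd + 2 * lam * sign(K[k, j]))
           else max(0, abs(gd) - 2 * lam)
    }
    worst <- max(worst, v)
  }
  if (!centered && !identical(fit$lambda_eta, "profiled")) {
    le <- fit$lambda_eta
    for (j in seq_len(m)) {
      gd <- grad[m + 1L, j]
      v <- if (le == 0 || eta[j] != 0) abs(gd + le * (sign(eta[j])))
           else max(0, abs(gd) - le)
      worst <- max(worst, v)
    }
  }
  worst
}

#' Find a kernel direction along which the unamplified loss is unbounded
#'
#' When n is small relative to m the blocks of \eqn{\Gamma} are rank
#' deficient and g need not be orthogonal to the kernel; along such a
#' direction \eqn{\nu} with \eqn{g^\top \nu \ne 0} the unpenalized loss
#' decreases linearly without bound. Returns the block index and the
#' direction (as a side x 1 vector within that block), or `NULL` when no
#' such direction is found among the blocks' null spaces.
#'
#' @param system An unamplified `sm_system`.
#' @param tol Eigenvalue threshold for the numerical kernel.
#' @return `NULL`, or list with `block`, `nu`, `g_dot_nu`.
#' @export
kernel_escape_direction <- function(system, tol = 1e-10) {
  side <- dim(system$blocks)[1]
  for (j in seq_len(system$m)) {
    ee <- eigen(system$blocks[, , j], symmetric = TRUE)
    null_idx <- which(ee$values < tol * max(ee$values, 1))
    for (i in null_idx) {
      nu <- ee$vectors[, i]
      gdn <- sum(system$g[, j] * nu)
      if (abs(gdn) > 1e-8)
        return(list(block = j, nu = nu, g_dot_nu = gdn))
    }
  }
  NULL
}

#' Plug-in sandwich covariance of the closed-form estimator
#'
#' Estimates the asymptotic covariance \eqn{\Gamma_0^{-1}\Sigma_0
#' \Gamma_0^{-1}/n} of the unpenalized estimator by plugging in the
#' empirical \eqn{\hat\Gamma} and the per-sample residuals
#' \eqn{\Gamma(x_i)\hat\theta - g(x_i)}. Dense in the full parameter; meant
#' for small m.
#'
#' @param x The data the system was built from (unscaled).
#' @param h,spec As in [build_system()].
#' @param fit An `sm_fit` from [closed_form()] (its `$psi` is used).
#' @return Covariance matrix of \eqn{vec(\Psi)} (column-stacked blocks).
#' @export
asymptotic_covariance <- function(x, h, spec, fit) {
  x <- as_data_matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (is.null(fit$psi)) abort("fit must come from closed_form().")
  side <- nrow(fit$psi)
  r <- side * m
  theta <- as.numeric(fit$psi)
  full <- build_system(x, h, spec)
  Gbar <- matrix(0, r, r)
  for (j in seq_len(m)) {
    idx <- (j - 1L) * side + seq_len(side)
    Gbar[idx, idx] <- full$blocks[, , j]
  }
  resid <- matrix(0, n, r)
  for (i in seq_len(n)) {
    si <- build_system(x[i, , drop = FALSE], h, spec)
    for (j in seq_len(m)) {
      idx <- (j - 1L) * side + seq_len(side)
      resid[i, idx] <- si$blocks[, , j] %*% fit$psi[, j] - si$g[, j]
    }
  }
  Sigma <- crossprod(resid) / n
  Ginv <- solve(Gbar)
  Ginv %*% Sigma %*% Ginv / n
}
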