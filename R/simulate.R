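#' Ground-truth interaction matrices for simulation
#'
#' `make_k0_block()` draws a block-diagonal K0 with `n_blocks` equal blocks:
#' within each block every lower-triangular element is zero with probability
#' `1 - pi` and otherwise drawn from Uniform(0.5, 1), then symmetrized. A
#' common diagonal value is then found by bisection so that the minimum
#' eigenvalue of K0 equals `min_eig` exactly (tolerance 1e-10).
#' `make_k0_er()` uses a global Erdos-Renyi edge mask instead of blocks,
#' with the same weight and diagonal scheme.
#'
#' @param m Number of variables.
#' @param pi Within-block (or global, for ER) edge probability.
#' @param n_blocks Number of equal diagonal blocks; must divide m.
#' @param seed Integer seed (RNG state is set and restored).
#' @param min_eig Target minimum eigenvalue of K0.
#' @return A `truth_model`: list with `K0`, `support` (ordered off-diagonal
#'   index pairs), `structure`, `pi`, `n_blocks`, `m`, `min_eig`, `seed`.
#' @examples
#' tm <- make_k0_block(10, pi = 0.2, n_blocks = 2, seed = 1)
#' min(eigen(tm$K0)$values) # 0.1
#' @export
make_k0_block <- function(m, pi, n_blocks, seed, min_eig = 0.1) {
  if (m %% n_blocks != 0) abort("n_blocks must divide m.")
  withr_seed(seed)
  bs <- m %/% n_blocks
  K <- matrix(0, m, m)
  for (b in seq_len(n_blocks)) {
    idx <- (b - 1L) * bs + seq_len(bs)
    B <- matrix(0, bs, bs)
    low <- which(lower.tri(B))
    on <- runif(length(low)) < pi
    B[low[on]] <- runif(sum(on), 0.5, 1)
    B <- B + t(B)
    K[idx, idx] <- B
  }
  finish_k0(K, m, min_eig, structure = "block", pi = pi,
            n_blocks = n_blocks, seed = seed)
}

#' @rdname make_k0_block
#' @param prob Global edge probability for the Erdos-Renyi structure.
#' @export
make_k0_er <- function(m, prob, seed, min_eig = 0.1) {
  withr_seed(seed)
  K <- matrix(0, m, m)
  low <- which(lower.tri(K))
  on <- runif(length(low)) < prob
  K[low[on]] <- runif(sum(on), 0.5, 1)
  K <- K + t(K)
  finish_k0(K, m, min_eig, structure = "erdos_renyi", pi = prob,
            n_blocks = 1L, seed = seed)
}

# raise a common diagonal until min eigenvalue == min_eig; a common shift
# moves every eigenvalue by the same amount, so the root is available in
# closed form (equivalent to, and exacter than, bisecting on the shift)
finish_k0 <- function(K, m, min_eig, structure, pi, n_blocks, seed) {
  lam_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  K <- K + diag(min_eig - lam_min, m)
  structure(list(K0 = K, support = support_pairs(K), structure = structure,
                 pi = pi, n_blocks = n_blocks, m = m, min_eig = min_eig,
                 seed = seed),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf(
    "<truth_model> m = %d, %s structure, %d edges, min eigenvalue %g\n",
    x$m, x$structure, nrow(x$support) %/% 2L, x$min_eig))
  invisible(x)
}

#' Gibbs sampler for the truncated multivariate normal on the orthant
#'
#' Density proportional to \eqn{\exp\{-(x-\mu)^\top K (x-\mu)/2\}} on
#' \eqn{[0,\infty)^m}. A single-chain Gibbs sampler whose coordinate
#' conditionals are univariate normals with mean
#' \eqn{\mu_j - \kappa_{jj}^{-1}\sum_{k\ne j}\kappa_{jk}(x_k-\mu_k)} and
#' variance \eqn{1/\kappa_{jj}}, truncated to \eqn{[0,\infty)}, drawn by a
#' rejection hybrid (plain normal rejection, switching to a shifted
#' exponential proposal when truncation is severe).
#'
#' @param n Number of samples to return.
#' @param truth A `truth_model`, or a PD matrix K0.
#' @param mu Mean parameter vector (default 0).
#' @param seed Integer seed.
#' @param burnin Sweeps discarded before recording.
#' @param thin Keep every `thin`-th sweep.
#' @return n x m matrix of non-negative samples.
#' @export
sample_truncated_normal <- function(n, truth, mu = NULL, seed = NULL,
                                    burnin = 500L, thin = 10L) {
  K <- if (inherits(truth, "truth_model")) truth$K0 else truth
  m <- nrow(K)
  if (is.null(mu)) mu <- rep(0, m)
  stopifnot(length(mu) == m)
  ev <- min(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) abort("K0 must be positive definite.")
  if (!is.null(seed)) withr_seed(seed)
  gibbs_tnorm_cpp(as.integer(n), unname(K), as.numeric(mu),
                  as.integer(burnin), as.integer(thin))
}

#' Gibbs sampler for pairwise interaction power models
#'
#' Coordinate-wise slice sampling (stepping out + shrinkage) on the
#' log-conditional
#' \eqn{-\kappa_{jj} x^{2a}/(2a) - x^a \sum_{k\ne j}\kappa_{jk} x_k^a
#'  + \eta_j (x^b - 1)/b} (with \eqn{\eta_j \log x} when b = 0).
#'
#' @inheritParams sample_truncated_normal
#' @param spec A [model_spec()].
#' @param K0 Interaction matrix.
#' @param eta0 Linear parameter (non-centered specs).
#' @return n x m matrix of samples (strictly positive when b = 0).
#' @export
sample_power_model <- function(n, spec, K0, eta0 = NULL, seed = NULL,
                               burnin = 500L, thin = 10L) {
  stopifnot(inherits(spec, "model_spec"))
  m <- nrow(K0)
  if (spec$centered) eta0 <- rep(0, m)
  if (is.null(eta0)) abort("eta0 required for a non-centered spec.")
  chk <- validate_parameters(spec, K0, if (spec$centered) NULL else eta0)
  if (!chk$ok) abort(paste0("invalid model parameters: ", chk$report))
  if (!is.null(seed)) withr_seed(seed)
  gibbs_power_cpp(as.integer(n), spec$a, spec$b, unname(K0),
                  as.numeric(eta0), spec$centered,
                  as.integer(burnin), as.integer(thin))
}

# set.seed without clobbering the caller's RNG stream on exit is deliberate:
# samplers are documented to consume (and reset) the global stream.
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}
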