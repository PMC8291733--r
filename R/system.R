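#' Build the empirical generalized h-score matching quadratic form
#'
#' For n samples from a pairwise interaction power model, the empirical
#' generalized h-score matching loss is the quadratic
#' \eqn{\frac12 \theta^\top \Gamma \theta - g^\top \theta} in
#' \eqn{\theta = vec(\Psi)}, \eqn{\Psi = (K^\top, \eta)^\top}, where
#' \eqn{\Gamma} is block-diagonal with one block per variable. The j-th
#' block (side m + 1 non-centered, m centered) and the matching linear
#' coefficients are sample averages involving h, h' and powers of the data:
#' \deqn{\Gamma_{11,j} = \frac1n \sum_i h_j(x_{ij}) x_{ij}^{2a-2}
#'       x_i^a x_i^{a\top},\quad
#'       \Gamma_{12,j} = -\frac1n \sum_i h_j(x_{ij}) x_{ij}^{a+b-2} x_i^a,\quad
#'       \Gamma_{22,j} = \frac1n \sum_i h_j(x_{ij}) x_{ij}^{2b-2},}
#' \deqn{g_{1,j} = \frac1n \sum_i [h_j'(x_{ij}) x_{ij}^{a-1} +
#'       (a-1) h_j(x_{ij}) x_{ij}^{a-2}] x_i^a
#'       + a\, h_j(x_{ij}) x_{ij}^{2a-2} e_j,\quad
#'       g_{2,j} = \frac1n \sum_i [-h_j'(x_{ij}) x_{ij}^{b-1}
#'       - (b-1) h_j(x_{ij}) x_{ij}^{b-2}],}
#' with the `b = 0` convention \eqn{d((x^b-1)/b)/dx = x^{b-1} = 1/x}.
#' Each unamplified block is an empirical second-moment (Gram) matrix and
#' hence positive semidefinite.
#'
#' @param x Data: numeric matrix or data frame, samples in rows, variables in
#'   columns; non-negative (strictly positive wherever a negative power of
#'   the data is required).
#' @param h An [h_function()] (or shorthand accepted by [parse_h()]).
#' @param spec A [model_spec()].
#' @param scale_columns If `TRUE`, divide each column by its l2 norm before
#'   building the system; the scales are recorded.
#' @return An object of class `sm_system`: list with `blocks` (side x side x m
#'   array), `g` (side x m matrix, column j = (g1_j; g2_j)), `m`, `n`, `spec`,
#'   `h`, `amplifier` (m x m matrix of diagonal additions, zero if
#'   unamplified), `delta` (multiplier, if set), `column_scales`, and
#'   `var_names`.
#' @examples
#' x <- matrix(c(1, 2), 1, 2)
#' sys <- build_system(x, h_power(2), model_spec("trunc_gaussian", centered = TRUE))
#' sys$blocks[, , 1] # [[1,2],[2,4]]
#' @export
build_system <- function(x, h, spec, scale_columns = FALSE) {
  h <- parse_h(h)
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family == "gaussian_rm")
    abort("use build_system_gaussian() for the R^m Gaussian model.")
  x <- as_data_matrix(x)
  if (any(x < 0)) abort("orthant models require non-negative data.")
  a <- spec$a; b <- spec$b; centered <- spec$centered
  n <- nrow(x); m <- ncol(x)
  if (m < 1 || n < 1) abort("need at least one sample and one variable.")
  scales <- rep(1, m)
  if (scale_columns) {
    sc <- scale_columns(x, root_n = TRUE)
    x <- sc$x
    scales <- sc$scales
  }
  # exponents actually applied to single coordinates (with nonzero coefficient)
  needed <- c(2 * a - 2, a - 1, if (a != 1) a - 2,
              if (!centered) c(a + b - 2, 2 * b - 2, b - 1,
                               if (b != 1) b - 2))
  if (any(needed < 0) && any(x == 0)) {
    idx <- which(x == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "zero data entry at (row %d, column %d) but a negative power of the data is required; model (a = %g, b = %g) needs strictly positive data",
      idx[1], idx[2], a, b))
  }
  side <- if (centered) m else m + 1L
  xa <- x^a
  pow0 <- function(p) if (p == 0) matrix(1, n, m) else x^p # 0^0 := 1
  hx <- apply(x, 2, function(col) h_evaluate(h, col))
  hpx <- apply(x, 2, function(col) h_derivative(h, col))
  dim(hx) <- dim(hpx) <- c(n, m)
  w11 <- hx * pow0(2 * a - 2)               # h_j(x_j) x_j^{2a-2}
  blocks <- array(0, dim = c(side, side, m))
  g <- matrix(0, side, m)
  if (!centered) {
    w12 <- hx * pow0(a + b - 2)
    w22 <- hx * pow0(2 * b - 2)
  }
  gw <- hpx * pow0(a - 1)
  if (a != 1) gw <- gw + (a - 1) * hx * pow0(a - 2)
  for (j in seq_len(m)) {
    G11 <- crossprod(xa, w11[, j] * xa) / n
    g1 <- colSums(gw[, j] * xa) / n
    g1[j] <- g1[j] + a * mean(w11[, j])
    if (centered) {
      blocks[, , j] <- (G11 + t(G11)) / 2
      g[, j] <- g1
    } else {
      G12 <- -colSums(w12[, j] * xa) / n
      G22 <- mean(w22[, j])
      Bj <- rbind(cbind(G11, G12), c(G12, G22))
      blocks[, , j] <- (Bj + t(Bj)) / 2
      g2 <- mean(-hpx[, j] * pow0(b - 1)[, j]) -
        (if (b != 1) (b - 1) * mean(hx[, j] * pow0(b - 2)[, j]) else 0)
      g[, j] <- c(g1, g2)
    }
  }
  new_sm_system(blocks, g, spec = spec, h = h, n = n,
                column_scales = scales, var_names = colnames(x))
}

new_sm_system <- function(blocks, g, spec, h, n, column_scales,
                          var_names = NULL, amplifier = NULL, delta = NULL) {
  m <- dim(blocks)[3]
  structure(list(
    blocks = blocks, g = g, m = m, n = n, spec = spec, h = h,
    amplifier = if (is.null(amplifier)) matrix(0, m, m) else amplifier,
    delta = delta, column_scales = column_scales,
    var_names = if (is.null(var_names)) paste0("V", seq_len(m)) else var_names),
    class = "sm_system")
}

#' @export
print.sm_system <- function(x, ...) {
  cat(sprintf(
    "<sm_system> m = %d variables, n = %d samples, %s blocks of side %d%s\n",
    x$m, x$n, if (x$spec$centered) "centered" else "non-centered",
    dim(x$blocks)[1],
    if (any(x$amplifier > 0))
      sprintf(", amplified%s", if (!is.null(x$delta))
        sprintf(" (multiplier %.4f)", x$delta) else "")
    else ", unamplified"))
  invisible(x)
}

is_amplified <- function(system) any(system$amplifier > 0)

#' Score matching system for the centered Gaussian on all of R^m
#'
#' For ordinary (untruncated) centered Gaussian data, the l1-regularized
#' score matching loss in K is
#' \eqn{\frac12 tr(K K x x^\top)/n - tr(K) + \lambda \|K\|_1}: every block of
#' \eqn{\Gamma} equals the second-moment matrix \eqn{x^\top x / n} and
#' \eqn{g = vec(I_m)}. Negative data values are allowed.
#'
#' @inheritParams build_system
#' @return An `sm_system` (centered; all blocks equal).
#' @export
build_system_gaussian <- function(x, scale_columns = FALSE) {
  x <- as_data_matrix(x)
  n <- nrow(x); m <- ncol(x)
  scales <- rep(1, m)
  if (scale_columns) {
    sc <- scale_columns(x, root_n = TRUE)
    x <- sc$x
    scales <- sc$scales
  }
  S <- crossprod(x) / n
  blocks <- array(S, dim = c(m, m, m))
  g <- diag(m)
  new_sm_system(blocks, g,
                spec = model_spec("gaussian_rm", centered = TRUE),
                h = h_constant(), n = n, column_scales = scales,
                var_names = colnames(x))
}

#' Generic exponential-family quadratic form from sufficient-statistic callbacks
#'
#' Builds the dense r x r quadratic form
#' \eqn{\Gamma = \frac1n \sum_i \sum_j h_j(x_{ij}) t_j'(x_i) t_j'(x_i)^\top}
#' and
#' \eqn{g = -\frac1n \sum_i \sum_j [h_j(x_{ij}) b_j'(x_i) t_j'(x_i)
#'  + h_j(x_{ij}) t_j''(x_i) + h_j'(x_{ij}) t_j'(x_i)]}
#' for an arbitrary exponential family
#' \eqn{\log p_\theta(x) = \theta^\top t(x) - \psi(\theta) + b(x)} on the
#' orthant, from user callbacks. Intended for small r (cross-checks,
#' univariate work); the power-model fast path is [build_system()].
#'
#' @inheritParams build_system
#' @param r Parameter dimension.
#' @param t_grad `function(x_row, j)` returning the r-vector
#'   \eqn{t_j'(x) = (\partial_j t_1(x), ..., \partial_j t_r(x))}.
#' @param t_hess_diag `function(x_row, j)` returning the r-vector
#'   \eqn{\partial_j t_j'(x)}.
#' @param b_grad `function(x_row, j)` returning the scalar
#'   \eqn{\partial_j b(x)}.
#' @return List with dense `Gamma` (r x r), `g` (r-vector), `n`.
#' @export
build_system_generic <- function(x, h, r, t_grad, t_hess_diag,
                                 b_grad = function(x_row, j) 0) {
  h <- parse_h(h)
  x <- as_data_matrix(x)
  n <- nrow(x); m <- ncol(x)
  Gamma <- matrix(0, r, r)
  g <- numeric(r)
  for (i in seq_len(n)) {
    xi <- x[i, ]
    for (j in seq_len(m)) {
      hj <- h_evaluate(h, xi[j])
      hpj <- h_derivative(h, xi[j])
      tg <- t_grad(xi, j)
      th <- t_hess_diag(xi, j)
      if (length(tg) != r || length(th) != r)
        abort("callback output dimension mismatch.")
      bg <- b_grad(xi, j)
      Gamma <- Gamma + hj * tcrossprod(tg)
      g <- g - (hj * bg * tg + hj * th + hpj * tg)
    }
  }
  list(Gamma = Gamma / n, g = g / n, n = n)
}

#' Scale data columns by their l2 norms
#'
#' With `root_n = FALSE` each column is divided by its plain l2 norm (unit-norm
#' columns). With `root_n = TRUE` the divisor is the l2 norm over sqrt(n)
#' (the column root mean square), which keeps data entries on their natural
#' O(1) scale; this is the convention used before estimation, so that
#' truncation points of bounded weight functions (e.g. `min(x, 3)`) retain
#' their meaning regardless of the sample size.
#'
#' @param x Matrix or data frame, samples in rows.
#' @param root_n Divide by l2 norm / sqrt(n) instead of the plain l2 norm.
#' @return List with `x` (scaled matrix) and `scales` (the divisors).
#' @export
scale_columns <- function(x, root_n = FALSE) {
  x <- as_data_matrix(x)
  scales <- sqrt(colSums(x^2))
  if (any(scales == 0)) abort("cannot scale an all-zero column.")
  if (root_n) scales <- scales / sqrt(nrow(x))
  list(x = sweep(x, 2, scales, "/"), scales = scales)
}

#' Amplify the diagonal of the quadratic form
#'
#' Adds positive amplifiers to the K-diagonal positions of each block (the
#' diagonal of \eqn{\Gamma_{11,j}}; \eqn{\Gamma_{22,j}} is untouched), which
#' makes the restricted quadratic form positive definite and the regularized
#' loss strongly convex, so a unique minimizer exists for every
#' \eqn{\lambda \ge 0} even when n <= m. The multiplier form sets
#' \eqn{\gamma = (\delta - 1)\,diag(\Gamma_{11,j})} per block; alternatively
#' an explicit positive m-vector `gamma` is applied to every block.
#'
#' @param system An unamplified `sm_system`.
#' @param delta Multiplier > 1, or exactly 1 for a no-op (no amplification).
#' @param gamma Positive m-vector of explicit diagonal additions.
#' @return The amplified `sm_system` (amplifier kept separate from the
#'   blocks, so model selection can use the unamplified form).
#' @export
amplify <- function(system, delta = NULL, gamma = NULL) {
  stopifnot(inherits(system, "sm_system"))
  if (is_amplified(system)) abort("system is already amplified.")
  if (is.null(delta) == is.null(gamma))
    abort("supply exactly one of delta or gamma.")
  m <- system$m
  if (!is.null(delta)) {
    if (delta == 1) return(system)
    if (delta < 1) abort("multiplier form requires delta > 1.")
    amp <- sapply(seq_len(m), function(j)
      (delta - 1) * diag(system$blocks[, , j])[seq_len(m)])
    system$delta <- delta
  } else {
    if (any(gamma <= 0)) abort("gamma entries must be positive.")
    amp <- matrix(rep(gamma, m), m, m)
  }
  system$amplifier <- matrix(amp, m, m)
  system
}

#' Consistency upper bound and medium default for the multiplier
#'
#' For truncated Gaussian graphical models with bounded h, support-recovery
#' consistency of the amplified estimator is guaranteed for multipliers
#' below
#' \deqn{C(n,m) = 2 - (1 + 4e\max\{\sqrt{6\log m/n},\, 6\log m/n\})^{-1},}
#' which is a practical default ("upper"); a lower "medium" default is
#' \eqn{2 - (1 + 24 e \log m / n)^{-1}}. Natural logarithm throughout.
#'
#' @param n Sample size (>= 1).
#' @param m Number of variables (>= 2).
#' @param kind `"upper"` or `"medium"`.
#' @return The multiplier value (a scalar in (1, 2)).
#' @examples
#' multiplier_bound(80, 100)    # 1.8647
#' multiplier_bound(1000, 100)  # 1.6438
#' @export
multiplier_bound <- function(n, m, kind = c("upper", "medium")) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, m >= 2)
  r <- log(m) / n
  if (kind == "upper") {
    2 - 1 / (1 + 4 * exp(1) * max(sqrt(6 * r), 6 * r))
  } else {
    2 - 1 / (1 + 24 * exp(1) * r)
  }
}

# coerce data frames (numeric columns) / matrices to a numeric matrix
as_data_matrix <- function(x) {
  if (is.data.frame(x)) {
    bad <- !vapply(x, is.numeric, logical(1))
    if (any(bad))
      abort(sprintf("non-numeric columns: %s",
                    paste(names(x)[bad], collapse = ", ")))
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("data contains missing values.")
  x
}
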