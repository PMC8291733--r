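#' Specify a pairwise interaction power model family
#'
#' The model family on the non-negative orthant has density
#' \deqn{p(x) \propto \exp\{-x^{a\top} K x^a / (2a) + \eta^\top (x^b - 1_m)/b\}}
#' with the convention \eqn{(x^0-1)/0 \equiv \log x}. Special cases:
#' truncated Gaussian (`a = b = 1`), exponential square-root (`a = b = 1/2`),
#' gamma (`a = 1/2, b = 0`). In the *centered* case \eqn{\eta \equiv 0} is
#' known and only the interaction matrix K is estimated. `family` may also be
#' `"gaussian_rm"`, the ordinary centered Gaussian on all of \eqn{R^m}
#' (handled by [build_system_gaussian()]).
#'
#' @param family One of `"trunc_gaussian"`, `"exponential"`, `"gamma"`,
#'   `"gaussian_rm"`, or `"general"` (supply `a`, `b` yourself).
#' @param a Positive interaction exponent.
#' @param b Non-negative linear-part exponent (`b = 0` requires strictly
#'   positive data).
#' @param centered If `TRUE`, \eqn{\eta \equiv 0} and only K is estimated.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("trunc_gaussian", centered = TRUE)
#' model_spec("general", a = 3/2, b = 1/2)
#' @export
model_spec <- function(family = c("general", "trunc_gaussian", "exponential",
                                  "gamma", "gaussian_rm"),
                       a = NULL, b = NULL, centered = FALSE) {
  family <- match.arg(family)
  defaults <- list(trunc_gaussian = c(1, 1), exponential = c(0.5, 0.5),
                   gamma = c(0.5, 0), gaussian_rm = c(1, 1))
  if (family != "general") {
    ab <- defaults[[family]]
    if (is.null(a)) a <- ab[1]
    if (is.null(b)) b <- ab[2]
    if (abs(a - ab[1]) > 1e-12 || abs(b - ab[2]) > 1e-12)
      abort(sprintf("family '%s' requires a = %g, b = %g", family,
                    ab[1], ab[2]))
  } else {
    if (is.null(a) || is.null(b)) abort("general family needs both a and b.")
  }
  stopifnot(a > 0, b >= 0)
  if (family == "gamma" && centered)
    family <- "exponential" # centered gamma loss never touches b
  structure(list(family = family, a = a, b = b, centered = centered),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (a = %g, b = %g, %s)\n", x$family, x$a, x$b,
              if (x$centered) "centered" else "non-centered"))
  invisible(x)
}

#' Check validity of model parameters
#'
#' Certifies that the density with interaction matrix `K` and linear
#' parameter `eta` is integrable over the orthant: K positive definite
#' (a sufficient condition for strict co-positivity, which is NP-hard to
#' verify in general) together with either a centered model, `2a > b > 0`,
#' or `b = 0` with every \eqn{\eta_j > -1}. When K is not PD but has
#' non-negative entries and a positive diagonal, the verdict is `FALSE` with
#' status `"copositivity unverified"` rather than a hard failure: strict
#' co-positivity (all that integrability needs) may still hold.
#'
#' @param spec A [model_spec()].
#' @param K Square interaction matrix.
#' @param eta Linear-part parameter vector; required for non-centered specs.
#' @return List with `ok` (logical) and `report` (character).
#' @export
validate_parameters <- function(spec, K, eta = NULL) {
  stopifnot(inherits(spec, "model_spec"), is.matrix(K),
            nrow(K) == ncol(K))
  m <- nrow(K)
  if (!spec$centered) {
    if (is.null(eta)) abort("non-centered spec: eta required.")
    if (length(eta) != m) abort("dimension mismatch between K and eta.")
  }
  ev_min <- min(eigen((K + t(K)) / 2, symmetric = TRUE,
                only.values = TRUE)$values)
  pd <- ev_min > 0
  if (!pd) {
    if (all(K >= 0) && all(diag(K) > 0)) {
      return(list(ok = FALSE,
                  report = "copositivity unverified: K not PD (non-negative entries, positive diagonal)"))
    }
    return(list(ok = FALSE, report = "K is not positive definite"))
  }
  if (spec$centered)
    return(list(ok = TRUE, report = "PD-verified; centered model"))
  if (spec$b > 0) {
    if (2 * spec$a > spec$b)
      list(ok = TRUE, report = "PD-verified; 2a > b > 0")
    else
      list(ok = FALSE, report = sprintf("2a > b fails (a = %g, b = %g)",
                                        spec$a, spec$b))
  } else {
    if (all(eta > -1))
      list(ok = TRUE, report = "PD-verified; b = 0 with all eta_j > -1")
    else
      list(ok = FALSE,
           report = sprintf("b = 0 requires eta_j > -1; offending j: %s",
                            paste(which(eta <= -1), collapse = ", ")))
  }
}
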