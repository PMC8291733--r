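#' Elementwise weight functions h for generalized score matching
#'
#' Generalized h-score matching weights the coordinatewise log-density
#' gradients by \eqn{\sqrt{h_j(x_j)}} before matching them to the data
#' distribution. An `h_function` describes one univariate weight, shared by
#' all coordinates: a non-negative, non-decreasing function on \eqn{[0,\infty)}
#' together with its a.e. derivative and its suprema `M = sup h`,
#' `Mprime = sup h'` (possibly infinite).
#'
#' Supported forms:
#' \describe{
#'   \item{`power`}{\eqn{h(x) = x^{p_1}}; `p1 = 2` recovers the original
#'     (Hyvarinen-type) score matching loss on the orthant.}
#'   \item{`truncated_power`}{\eqn{h(x) = \min(x^{p_1}, c)}.}
#'   \item{`log1p_truncated`}{\eqn{h(x) = \min(\log(1+x), c)}.}
#'   \item{`mcp`, `scad`}{the MCP / SCAD penalty functions of
#'     sparse regression, used here as smooth bounded weights; parameters
#'     `pen_lambda`, `pen_gamma`.}
#'   \item{`constant`}{\eqn{h \equiv 1}; valid for score matching on all of
#'     \eqn{R^m} and for the known-mean univariate variance estimator, but
#'     not admissible for orthant models (its limit at 0 is not 0).}
#' }
#'
#' @param form One of `"power"`, `"truncated_power"`, `"log1p_truncated"`,
#'   `"mcp"`, `"scad"`, `"constant"`.
#' @param p1 Non-negative exponent (power forms).
#' @param c Positive truncation point, may be `Inf`.
#' @param pen_lambda,pen_gamma Positive MCP/SCAD shape parameters.
#' @return An object of class `h_function` with fields `form`, `p1`, `c`,
#'   `pen_lambda`, `pen_gamma`, `M`, `Mprime`.
#' @examples
#' h <- h_function("truncated_power", p1 = 1, c = 3)
#' h_evaluate(h, c(0.5, 5)) # 0.5, 3
#' @export
h_function <- function(form = c("power", "truncated_power", "log1p_truncated",
                                "mcp", "scad", "constant"),
                       p1 = 1, c = Inf, pen_lambda = 1, pen_gamma = 10) {
  form <- match.arg(form)
  if (form %in% c("power", "truncated_power")) {
    stopifnot(is.numeric(p1), length(p1) == 1L, p1 >= 0)
  }
  if (form %in% c("truncated_power", "log1p_truncated")) {
    stopifnot(is.numeric(c), length(c) == 1L, c > 0)
  }
  if (form %in% c("mcp", "scad")) {
    stopifnot(pen_lambda > 0, pen_gamma > 0)
    if (form == "scad" && pen_gamma <= 1)
      abort("SCAD requires pen_gamma > 1.")
  }
  M <- switch(form,
    power = if (p1 == 0) 1 else Inf,
    truncated_power = if (p1 == 0) 1 else c,
    log1p_truncated = c,
    mcp = pen_gamma * pen_lambda^2 / 2,
    scad = pen_lambda^2 * (pen_gamma + 1) / 2,
    constant = 1)
  Mprime <- switch(form,
    power = if (p1 == 0) 0 else if (p1 == 1) 1 else if (p1 < 1) Inf else Inf,
    truncated_power = if (p1 == 0) 0 else if (p1 == 1) 1
                      else if (p1 < 1) Inf else p1 * c^((p1 - 1) / p1),
    log1p_truncated = 1,
    mcp = pen_lambda,
    scad = pen_lambda,
    constant = 0)
  structure(
    list(form = form, p1 = if (form == "constant") 0 else p1, c = c,
         pen_lambda = pen_lambda, pen_gamma = pen_gamma,
         M = M, Mprime = Mprime),
    class = "h_function")
}

#' @rdname h_function
#' @export
h_power <- function(p1 = 1) h_function("power", p1 = p1)

#' @rdname h_function
#' @export
h_truncated_power <- function(p1 = 1, c = Inf)
  h_function("truncated_power", p1 = p1, c = c)

#' @rdname h_function
#' @export
h_log1p <- function(c = Inf) h_function("log1p_truncated", c = c)

#' @rdname h_function
#' @export
h_mcp <- function(pen_lambda = 1, pen_gamma = 10)
  h_function("mcp", pen_lambda = pen_lambda, pen_gamma = pen_gamma)

#' @rdname h_function
#' @export
h_scad <- function(pen_lambda = 1, pen_gamma = 10)
  h_function("scad", pen_lambda = pen_lambda, pen_gamma = pen_gamma)

#' @rdname h_function
#' @export
h_constant <- function() h_function("constant")

#' @export
print.h_function <- function(x, ...) {
  desc <- switch(x$form,
    power = sprintf("x^%g", x$p1),
    truncated_power = if (is.finite(x$c)) sprintf("min(x^%g, %g)", x$p1, x$c)
                      else sprintf("x^%g", x$p1),
    log1p_truncated = if (is.finite(x$c)) sprintf("min(log(1+x), %g)", x$c)
                      else "log(1+x)",
    mcp = sprintf("MCP(%g, %g)", x$pen_lambda, x$pen_gamma),
    scad = sprintf("SCAD(%g, %g)", x$pen_lambda, x$pen_gamma),
    constant = "1")
  cat("<h_function> h(x) =", desc,
      sprintf("[M = %g, M' = %g]\n", x$M, x$Mprime))
  invisible(x)
}

#' Evaluate a weight function or its derivative
#'
#' `h_evaluate()` applies h elementwise; `h_derivative()` applies its a.e.
#' derivative, returning the left derivative at kink points (a measure-zero
#' set, irrelevant for continuous data).
#'
#' @param h An [h_function()].
#' @param x Numeric vector of non-negative values.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' h_derivative(h_power(2), 3) # 6
#' @export
h_evaluate <- function(h, x) {
  stopifnot(inherits(h, "h_function"))
  if (any(x < 0)) abort("h is defined on [0, Inf): negative input.")
  switch(h$form,
    power = x^h$p1,
    truncated_power = pmin(x^h$p1, h$c),
    log1p_truncated = pmin(log1p(x), h$c),
    mcp = {
      l <- h$pen_lambda; g <- h$pen_gamma
      ifelse(x <= g * l, l * x - x^2 / (2 * g), g * l^2 / 2)
    },
    scad = {
      l <- h$pen_lambda; g <- h$pen_gamma
      ifelse(x <= l, l * x,
        ifelse(x < g * l,
          (2 * g * l * x - x^2 - l^2) / (2 * (g - 1)),
          l^2 * (g + 1) / 2))
    },
    constant = rep(1, length(x)))
}

#' @rdname h_evaluate
#' @export
h_derivative <- function(h, x) {
  stopifnot(inherits(h, "h_function"))
  if (any(x < 0)) abort("h is defined on [0, Inf): negative input.")
  switch(h$form,
    power = if (h$p1 == 0) rep(0, length(x)) else h$p1 * x^(h$p1 - 1),
    truncated_power = {
      if (h$p1 == 0) rep(0, length(x))
      else ifelse(x^h$p1 <= h$c, h$p1 * x^(h$p1 - 1), 0)
    },
    log1p_truncated = ifelse(log1p(x) <= h$c, 1 / (1 + x), 0),
    mcp = {
      l <- h$pen_lambda; g <- h$pen_gamma
      ifelse(x <= g * l, l - x / g, 0)
    },
    scad = {
      l <- h$pen_lambda; g <- h$pen_gamma
      ifelse(x <= l, l, ifelse(x < g * l, (g * l - x) / (g - 1), 0))
    },
    constant = rep(0, length(x)))
}

# small-x power-law exponent of each parametric form (h(x) ~ const * x^e)
h_small_x_exponent <- function(h) {
  switch(h$form,
    power = h$p1,
    truncated_power = h$p1,
    log1p_truncated = 1,  # log(1+x) ~ x
    mcp = 1,              # lambda*x - x^2/(2 gamma) ~ lambda*x
    scad = 1,             # lambda*x
    constant = 0)
}

#' Check admissibility of h for a pairwise interaction power model
#'
#' A weight function is admissible for the (a, b) model family when (i) it is
#' absolutely continuous on bounded sub-intervals, (ii) positive a.e. on
#' \eqn{(0,\infty)}, (iii) bounded with its derivative by piecewise powers,
#' and (iv) \eqn{\lim_{x \downarrow 0} h(x)/x^q = 0} with
#' \eqn{q = \max(1-a, 1-b)} when `b > 0` and \eqn{q = 1 - \min_j \eta_{0j}}
#' when `b = 0`. All supported parametric forms satisfy (i)-(iii); (iv) is
#' checked symbolically as a strict inequality between the small-x power-law
#' exponent of h and q (an exponent exactly equal to q gives a nonzero limit
#' and is rejected).
#'
#' @param h An [h_function()].
#' @param a Positive interaction exponent.
#' @param b Non-negative linear-part exponent.
#' @param eta_min Lower bound on the components of \eqn{\eta_0}, required when
#'   `b = 0`; use the worst case `-1` when unknown.
#' @return A list with `ok` (logical) and `report` (character) stating which
#'   condition fails, if any.
#' @examples
#' h_membership(h_truncated_power(1, 3), a = 1, b = 1)$ok   # TRUE
#' h_membership(h_constant(), a = 1, b = 1)$ok              # FALSE
#' @export
h_membership <- function(h, a, b, eta_min = -1) {
  stopifnot(inherits(h, "h_function"), a > 0, b >= 0)
  if (h$form == "constant")
    return(list(ok = FALSE,
                report = "condition iv fails: lim h(x) at 0+ is 1, not 0"))
  q <- if (b > 0) max(1 - a, 1 - b) else 1 - eta_min
  e <- h_small_x_exponent(h)
  if (e > q) {
    list(ok = TRUE,
         report = sprintf("admissible: small-x exponent %g > q = %g", e, q))
  } else {
    list(ok = FALSE,
         report = sprintf(
           "condition iv fails: h(x)/x^q with q = %g does not vanish (small-x exponent %g)",
           q, e))
  }
}

#' Parse a weight-function shorthand
#'
#' Accepts strings such as `"x"`, `"x^2"`, `"min(x,3)"`, `"min(x^1.5,2)"`,
#' `"log1p"`, `"min(log(1+x),2)"`, `"mcp(1,10)"`, `"scad(1,10)"`, `"1"`.
#'
#' @param spec A character scalar, or a list with a `form` field (passed to
#'   [h_function()]), or an `h_function` (returned unchanged).
#' @return An [h_function()].
#' @export
parse_h <- function(spec) {
  if (inherits(spec, "h_function")) return(spec)
  if (is.list(spec)) return(do.call(h_function, spec))
  stopifnot(is.character(spec), length(spec) == 1L)
  s <- gsub(" ", "", tolower(spec))
  num <- "([0-9.]+|inf)"
  as_num <- function(t) if (t == "inf") Inf else as.numeric(t)
  if (s %in% c("1", "constant")) return(h_constant())
  if (s == "x") return(h_power(1))
  if (grepl("^x\\^", s)) return(h_power(as.numeric(sub("^x\\^", "", s))))
  if (s %in% c("log1p", "log(1+x)")) return(h_log1p(Inf))
  mm <- regmatches(s, regexec(paste0("^min\\(log\\(1\\+x\\),", num, "\\)$"), s))[[1]]
  if (length(mm)) return(h_log1p(as_num(mm[2])))
  mm <- regmatches(s, regexec(paste0("^min\\(x,", num, "\\)$"), s))[[1]]
  if (length(mm)) return(h_truncated_power(1, as_num(mm[2])))
  mm <- regmatches(s, regexec(paste0("^min\\(x\\^", num, ",", num, "\\)$"), s))[[1]]
  if (length(mm)) return(h_truncated_power(as.numeric(mm[2]), as_num(mm[3])))
  mm <- regmatches(s, regexec(paste0("^(mcp|scad)\\(", num, ",", num, "\\)$"), s))[[1]]
  if (length(mm))
    return(h_function(mm[2], pen_lambda = as.numeric(mm[3]),
                      pen_gamma = as.numeric(mm[4])))
  abort(sprintf("cannot parse h specification '%s'", spec))
}

#' @export
autoplot.h_function <- function(object, xlim = c(0, 5), n = 401, ...) {
  grid <- seq(xlim[1], xlim[2], length.out = n)
  df <- tibble::tibble(
    x = rep(grid, 2),
    value = c(h_evaluate(object, grid), h_derivative(object, grid)),
    what = rep(c("h(x)", "h'(x)"), each = n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "x", y = NULL)
}
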