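#' Edge-recovery true/false positive rates
#'
#' Counts ordered off-diagonal pairs exactly as in the benchmark
#' definitions:
#' \deqn{FPR = \frac{|\hat S_{off} \setminus S_{0,off}|}{m(m-1) -
#' |S_{0,off}|}, \qquad TPR = \frac{|\hat S_{off} \cap S_{0,off}|}
#' {|S_{0,off}|}.}
#' Symmetric supports make this equivalent to unordered counting.
#'
#' @param est_support,true_support Two-column matrices of ordered
#'   off-diagonal index pairs (as produced in `sm_fit$support` /
#'   `truth_model$support`).
#' @param m Number of variables.
#' @return List with `tpr`, `fpr`.
#' @export
tpr_fpr <- function(est_support, true_support, m) {
  nt <- nrow(true_support)
  if (nt == 0) abort("true support is empty: TPR undefined.")
  key <- function(s) if (nrow(s) == 0) integer(0)
                     else (s[, 1] - 1L) * m + s[, 2]
  est <- key(est_support); tru <- key(true_support)
  tp <- sum(est %in% tru)
  fp <- length(est) - tp
  list(tpr = tp / nt, fpr = fp / (m * (m - 1) - nt))
}

#' ROC curve of a regularization path against a known graph
#'
#' One (FPR, TPR) point per path entry, sorted by FPR, with the TPR made
#' non-decreasing by its running maximum (monotone envelope) and the
#' endpoints (0,0) and (1,1) appended; AUC by the trapezoid rule.
#'
#' @param path An `sm_path` (or a list of `sm_fit`s).
#' @param true_support Ordered off-diagonal pairs of the true graph.
#' @param m Number of variables.
#' @return An `roc_curve`: list with `fpr`, `tpr`, `auc`,
#'   `n_curves_averaged = 1`.
#' @export
roc_from_path <- function(path, true_support, m) {
  fits <- if (inherits(path, "sm_path")) path$fits else path
  pts <- vapply(fits, function(f) {
    r <- tpr_fpr(f$support, true_support, m)
    c(r$fpr, r$tpr)
  }, numeric(2))
  ord <- order(pts[1, ], pts[2, ])
  fpr <- c(0, pts[1, ord], 1)
  tpr <- c(0, cummax(pts[2, ord]), 1)
  new_roc(fpr, tpr, n = 1L)
}

new_roc <- function(fpr, tpr, n) {
  keep <- !duplicated(cbind(fpr, tpr))
  fpr <- fpr[keep]; tpr <- tpr[keep]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc, n_curves_averaged = n),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d curve%s averaged, %d points)\n",
              x$auc, x$n_curves_averaged,
              if (x$n_curves_averaged == 1) "" else "s", length(x$fpr)))
  invisible(x)
}

#' Vertical averaging of ROC curves
#'
#' Each curve's TPR is linearly interpolated on a common FPR grid and
#' averaged pointwise; this averaging preserves the mean AUC up to the grid
#' resolution (within about 2/`grid_size`).
#'
#' @param curves List of `roc_curve`s.
#' @param grid_size Number of FPR grid points.
#' @return An averaged `roc_curve`.
#' @export
vertical_average <- function(curves, grid_size = 1001L) {
  if (length(curves) == 0) abort("no curves to average.")
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(curves, function(cv)
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y,
    numeric(grid_size))
  new_roc(grid, rowMeans(matrix(tprs, ncol = length(curves))),
          n = sum(vapply(curves, function(cv) cv$n_curves_averaged,
                         integer(1))))
}

#' Hypergeometric tail probability of graph edge overlap
#'
#' Under the null that two graphs on the same m nodes place their edges
#' uniformly at random and independently, the number R of shared edges is
#' hypergeometric over the \eqn{N = m(m-1)/2} node pairs. Returns the
#' upper-tail probability \eqn{P(R \ge overlap)}.
#'
#' @param m Number of nodes.
#' @param edges_a,edges_b Edge counts of the two graphs (unordered pairs).
#' @param overlap Observed shared edges.
#' @return Upper-tail p-value.
#' @examples
#' edge_overlap_pvalue(3, 1, 1, 1) # 1/3
#' @export
edge_overlap_pvalue <- function(m, edges_a, edges_b, overlap) {
  N <- m * (m - 1) / 2
  stopifnot(edges_a <= N, edges_b <= N,
            overlap <= min(edges_a, edges_b), overlap >= 0)
  r <- overlap:min(edges_a, edges_b)
  sum(dhyper(r, edges_a, N - edges_a, edges_b))
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tibble::tibble(fpr = object$fpr, tpr = object$tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}
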