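#' Tidy an estimated interaction matrix into an edge table
#'
#' One row per unordered off-diagonal pair with a nonzero estimate.
#'
#' @param x An `sm_fit`.
#' @param ... Unused.
#' @return Tibble with `node_i`, `node_j`, `kappa_hat` (i < j positions).
#' @export
tidy.sm_fit <- function(x, ...) {
  K <- x$K
  idx <- which(abs(K) > 0 & upper.tri(K), arr.ind = TRUE)
  tibble::tibble(
    node_i = x$var_names[idx[, 1]],
    node_j = x$var_names[idx[, 2]],
    kappa_hat = K[idx])
}

#' @rdname tidy.sm_fit
#' @export
glance.sm_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, n = x$n,
    lambda_K = x$lambda_K,
    lambda_eta = if (identical(x$lambda_eta, "profiled")) NA_real_
                 else x$lambda_eta,
    profiled = identical(x$lambda_eta, "profiled"),
    n_edges = sum(x$K[upper.tri(x$K)] != 0),
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged)
}

#' Tidy a regularization path
#'
#' @param x An `sm_path`.
#' @param ... Unused.
#' @return Tibble with one row per lambda: `lambda`, `n_edges`, `objective`,
#'   `converged`, `ebic` (NA until [ebic_select()] has been run).
#' @export
tidy.sm_path <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambdas,
    n_edges = x$edge_counts,
    objective = vapply(x$fits, function(f) f$objective, numeric(1)),
    converged = vapply(x$fits, function(f) f$converged, logical(1)),
    ebic = x$ebic)
}

#' @export
autoplot.sm_path <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$lambda > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$n_edges)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "off-diagonal edges")
}

#' @rdname tidy.sm_fit
#' @export
tidy.benchmark_result <- function(x, ...) {
  tibble::tibble(curve = seq_along(x$aucs), auc = x$aucs)
}

#' @rdname tidy.sm_fit
#' @export
glance.benchmark_result <- function(x, ...) {
  tibble::tibble(n_curves = length(x$aucs), mean_auc = x$mean_auc,
                 sd_auc = x$sd_auc)
}

#' @export
autoplot.benchmark_result <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(
      subtitle = sprintf("mean AUC = %.3f (sd %.3f, %d curves)",
                         object$mean_auc, object$sd_auc,
                         length(object$aucs)))
}
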