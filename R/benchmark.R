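#' Edge-recovery benchmark: simulate, fit paths, average ROC curves
#'
#' Runs the full simulation pipeline for one scenario: draw `n_k0` true
#' interaction matrices, sample `n_rep` data sets from each (so
#' `n_k0 * n_rep` curves in total), column-scale, build and amplify the
#' score matching system, fit a lambda path (with a lambda = 0 closed-form
#' endpoint so curves reach FPR = 1), compute a per-trial ROC curve, and
#' vertically average. Per-curve seeds are derived from `seed` as
#' `seed + 1000 * k0_index + rep_index` (and `seed + 1000 * k0_index` for
#' the K0 draw), so the whole summary is reproducible from one integer.
#'
#' @param scenario A list as produced by [benchmark_scenario()].
#' @param seed Master integer seed.
#' @param progress Print one line per curve.
#' @return A `benchmark_result`: list with `roc` (the vertically averaged
#'   `roc_curve`), `aucs` (per-curve vector), `mean_auc`, `sd_auc`,
#'   `ebic_points` (tibble of eBIC-selected operating points, when
#'   requested) and the `scenario`.
#' @export
run_benchmark <- function(scenario, seed = 1L, progress = FALSE) {
  sc <- scenario
  spec <- sc$spec
  curves <- list()
  ebic_rows <- list()
  for (k in seq_len(sc$n_k0)) {
    k0_seed <- seed + 1000L * k
    truth <- if (sc$structure == "block")
      make_k0_block(sc$m, pi = sc$pi, n_blocks = sc$n_blocks, seed = k0_seed)
    else
      make_k0_er(sc$m, prob = sc$pi, seed = k0_seed)
    if (nrow(truth$support) == 0) {
      warn(sprintf("K0 %d has no edges; skipping (TPR undefined)", k))
      next
    }
    for (r in seq_len(sc$n_rep)) {
      rep_seed <- k0_seed + r
      mu <- NULL
      if (!spec$centered && identical(spec$family, "trunc_gaussian")) {
        withr_seed(rep_seed * 2L + 1L)
        mu <- rnorm(sc$m, 0, 0.5) # mu0 components iid N(0, 0.5^2)
      }
      x <- if (identical(spec$family, "trunc_gaussian"))
        sample_truncated_normal(sc$n, truth, mu = mu, seed = rep_seed,
                                burnin = sc$burnin, thin = sc$thin)
      else
        sample_power_model(sc$n, spec, truth$K0, eta0 = sc$eta0,
                           seed = rep_seed, burnin = sc$burnin,
                           thin = sc$thin)
      sys <- build_system(x, sc$h, spec, scale_columns = TRUE)
      if (sc$delta > 1) sys <- amplify(sys, delta = sc$delta)
      path <- fit_path(sys, n_lambda = sc$n_lambda,
                       lambda_min_ratio = sc$lambda_min_ratio,
                       lambda_eta_rule = sc$lambda_eta_rule,
                       penalize_diag = sc$penalize_diag, tol = sc$tol,
                       max_iter = sc$max_iter, include_zero = TRUE)
      roc <- roc_from_path(path, truth$support, sc$m)
      curves[[length(curves) + 1L]] <- roc
      if (isTRUE(sc$ebic_points)) {
        sel <- ebic_select(path, sys, refit = TRUE)
        rr <- tpr_fpr(sel$fit$support, truth$support, sc$m)
        ebic_rows[[length(ebic_rows) + 1L]] <- tibble::tibble(
          k0 = k, rep = r, lambda = sel$lambda, tpr = rr$tpr, fpr = rr$fpr)
      }
      if (progress)
        message(sprintf("K0 %d rep %d: AUC %.4f", k, r, roc$auc))
    }
  }
  if (length(curves) == 0) abort("no usable curves (all K0 empty?).")
  aucs <- vapply(curves, function(cv) cv$auc, numeric(1))
  structure(list(
    roc = vertical_average(curves), aucs = aucs, mean_auc = mean(aucs),
    sd_auc = stats::sd(aucs),
    ebic_points = if (length(ebic_rows)) dplyr::bind_rows(ebic_rows) else NULL,
    scenario = sc), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> %d curves: mean AUC %.4f (sd %.4f)\n",
    length(x$aucs), x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Describe one benchmark scenario
#'
#' Bundles the study conditions for [run_benchmark()]. Defaults mirror the
#' standard truncated-GGM design: block-structured K0 with 10 equal blocks,
#' off-diagonal weights Uniform(0.5, 1), minimum eigenvalue 0.1, Gibbs
#' sampling with burn-in 500 and thinning 10, column scaling, a 50-point
#' lambda path down to 1e-4 of lambda_max.
#'
#' @param m,n Problem dimensions.
#' @param spec A [model_spec()].
#' @param h Weight function (or shorthand).
#' @param delta Multiplier (1 = no amplification).
#' @param pi Edge probability (within blocks, or global for `"erdos_renyi"`).
#' @param structure `"block"` or `"erdos_renyi"`.
#' @param n_blocks Number of K0 blocks.
#' @param n_k0 Number of true matrices; `n_rep` data replicates each.
#' @param n_rep Replicates per K0.
#' @param eta0 True eta for non-Gaussian non-centered families.
#' @param lambda_eta_rule,penalize_diag,n_lambda,lambda_min_ratio,tol,max_iter
#'   Passed to [fit_path()].
#' @param burnin,thin Gibbs settings.
#' @param ebic_points Also record eBIC-selected operating points.
#' @return A named list (class `benchmark_scenario`).
#' @export
benchmark_scenario <- function(m, n, spec, h, delta = 1, pi = 0.2,
                               structure = "block", n_blocks = 10L,
                               n_k0 = 5L, n_rep = 10L, eta0 = NULL,
                               lambda_eta_rule = if (spec$centered) "fixed"
                                                 else "profiled",
                               penalize_diag = FALSE, n_lambda = 50L,
                               lambda_min_ratio = 1e-4, tol = 1e-6,
                               max_iter = 1000L, burnin = 500L, thin = 10L,
                               ebic_points = FALSE) {
  out <- list(m = m, n = n, spec = spec, h = parse_h(h), delta = delta,
              pi = pi, structure = structure, n_blocks = n_blocks,
              n_k0 = n_k0, n_rep = n_rep, eta0 = eta0,
              lambda_eta_rule = lambda_eta_rule,
              penalize_diag = penalize_diag, n_lambda = n_lambda,
              lambda_min_ratio = lambda_min_ratio, tol = tol,
              max_iter = max_iter, burnin = burnin, thin = thin,
              ebic_points = ebic_points)
  class(out) <- "benchmark_scenario"
  out
}
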