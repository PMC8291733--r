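pairs_of <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

test_that("TPR/FPR follow the ordered-pair definitions", {
  S0 <- pairs_of(1, 2, 2, 1)
  Sh <- pairs_of(1, 2, 2, 1, 1, 3, 3, 1)
  r <- tpr_fpr(Sh, S0, m = 3)
  expect_equal(r$tpr, 1)
  expect_equal(r$fpr, 0.5) # 2 false ordered pairs / (6 - 2)
  expect_equal(tpr_fpr(S0, S0, 3), list(tpr = 1, fpr = 0))
  expect_equal(tpr_fpr(S0[0, ], S0, 3), list(tpr = 0, fpr = 0))
  expect_error(tpr_fpr(S0, S0[0, ], 3), "undefined")
})

test_that("ROC construction covers the degenerate paths", {
  S0 <- pairs_of(1, 2, 2, 1)
  empty_fit <- list(support = S0[0, , drop = FALSE])
  r <- roc_from_path(list(empty_fit), S0, 3)
  expect_equal(r$fpr, c(0, 1))
  expect_equal(r$auc, 0.5)
  oracle <- list(support = S0)
  expect_equal(roc_from_path(list(empty_fit, oracle), S0, 3)$auc, 1)
  # duplicated entries leave the AUC unchanged
  expect_equal(roc_from_path(list(oracle, oracle, empty_fit), S0, 3)$auc, 1)
})

test_that("vertical averaging preserves the mean AUC", {
  diag_curve <- roc_from_path(list(list(support = matrix(0, 0, 2))),
                              pairs_of(1, 2, 2, 1), 3)
  perfect <- roc_from_path(list(list(support = pairs_of(1, 2, 2, 1))),
                           pairs_of(1, 2, 2, 1), 3)
  avg <- vertical_average(list(diag_curve, perfect))
  expect_equal(avg$auc, 0.75, tolerance = 0.002)
  expect_equal(avg$n_curves_averaged, 2L)
  same <- vertical_average(list(perfect, perfect))
  expect_equal(same$auc, perfect$auc, tolerance = 0.002)
  single <- vertical_average(list(diag_curve))
  expect_equal(single$auc, 0.5, tolerance = 0.002)
  expect_error(vertical_average(list()), "no curves")
  # random curves: averaged AUC = mean of member AUCs within grid tolerance
  set.seed(5)
  rocs <- lapply(1:6, function(i) {
    fp <- sort(runif(8)); tp <- sort(runif(8))
    hscore:::new_roc(c(0, fp, 1), c(0, tp, 1), 1L)
  })
  avg2 <- vertical_average(rocs, grid_size = 2001)
  expect_lt(abs(avg2$auc - mean(sapply(rocs, `[[`, "auc"))), 2 / 2001)
})

test_that("monotone-envelope invariants hold on fitted paths", {
  sys <- random_amplified_system(n = 30, m = 5, seed = 16)
  p <- fit_path(sys, n_lambda = 10, lambda_min_ratio = 1e-3,
                include_zero = TRUE)
  truth <- pairs_of(1, 2, 2, 1, 3, 4, 4, 3)
  r <- roc_from_path(p, truth, 5)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
})

test_that("edge overlap p-value matches the hypergeometric by hand", {
  # m = 3: N = 3 pairs; one edge each; P(share) = 1/3
  expect_equal(edge_overlap_pvalue(3, 1, 1, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(edge_overlap_pvalue(3, 1, 1, 0), 1)
  # complete graph forces full overlap
  expect_equal(edge_overlap_pvalue(4, 6, 3, 3), 1)
  # cross-check a nontrivial case against direct enumeration
  expect_equal(edge_overlap_pvalue(5, 4, 3, 2),
               sum(dhyper(2:3, 4, 6, 3)), tolerance = 1e-12)
  expect_error(edge_overlap_pvalue(3, 1, 1, 2), "overlap")
})

test_that("a small full benchmark is deterministic and sane", {
  sc <- benchmark_scenario(m = 20, n = 40,
                           spec = model_spec("trunc_gaussian",
                                             centered = TRUE),
                           h = "min(x,3)", delta = multiplier_bound(40, 20),
                           pi = 0.5, n_blocks = 4, n_k0 = 2, n_rep = 2,
                           n_lambda = 15, burnin = 200, thin = 3)
  b1 <- run_benchmark(sc, seed = 9)
  b2 <- run_benchmark(sc, seed = 9)
  expect_identical(b1$aucs, b2$aucs)
  expect_length(b1$aucs, 4)
  expect_true(all(b1$aucs > 0.5)) # far better than chance at this size
  expect_equal(b1$roc$auc, b1$mean_auc, tolerance = 0.01)
  expect_s3_class(glance(b1), "tbl_df")
})

test_that("scenarios whose truth has no edges are skipped with a warning", {
  sc <- benchmark_scenario(m = 10, n = 30,
                           spec = model_spec("trunc_gaussian",
                                             centered = TRUE),
                           h = "x", delta = 1.5, pi = 0,
                           n_blocks = 10, n_k0 = 1, n_rep = 1,
                           n_lambda = 5, burnin = 50, thin = 1)
  expect_warning(expect_error(run_benchmark(sc, seed = 1), "no usable"),
                 "no edges")
})
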