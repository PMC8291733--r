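test_that("closed form solves tiny systems by hand", {
  # identity system: estimate = g
  sys <- random_amplified_system(m = 3, seed = 1)
  sys$blocks <- array(diag(4), dim = c(4, 4, 3))
  sys$amplifier <- matrix(0, 3, 3)
  sys$g <- matrix(1:12, 4, 3)
  cf <- closed_form(sys, symmetrize = FALSE)
  expect_equal(unname(cf$psi), matrix(1:12, 4, 3))
  # univariate truncated normal with h(x) = x, sigma2 = 1, data {1,2}:
  # the m = 1 block solve reduces to the Example 3.1 ratio = 1
  x <- matrix(c(1, 2), 2, 1)
  s1 <- build_system(x, "x", model_spec("trunc_gaussian", centered = TRUE))
  expect_equal(estimate_mu(c(1, 2), 1, "x"), 1)
  # and the non-centered m=1 closed form is the per-block linear solve
  s2 <- build_system(x, "x", model_spec("trunc_gaussian"))
  f2 <- closed_form(s2)
  expect_equal(as.numeric(f2$psi), solve(s2$blocks[, , 1], s2$g[, 1]),
               tolerance = 1e-12)
})

test_that("column-decoupled coordinate descent reproduces the closed form", {
  for (seed in 1:5) {
    sys <- random_amplified_system(seed = seed, centered = seed %% 2 == 0)
    cf <- closed_form(sys, symmetrize = FALSE)
    cd <- solve_regularized(sys, 0, tol = 1e-12, max_iter = 5000,
                            symmetric = FALSE)
    expect_lt(max(abs(cf$psi[1:5, ] - unname(cd$K))), 1e-6)
    if (!is.null(cf$eta)) expect_lt(max(abs(cf$psi[6, ] - cd$eta)), 1e-6)
  }
})

test_that("KKT conditions hold at convergence across lambda values", {
  sys <- random_amplified_system(seed = 7)
  for (lam in c(0, 1e-4, 1e-3, 1e-2, 0.1)) {
    fit <- solve_regularized(sys, lam)
    expect_lt(kkt_violation(sys, fit), 1e-6)
  }
  # also in the no-diagonal-penalty and penalized-eta variants
  f2 <- solve_regularized(sys, 0.01, penalize_diag = FALSE)
  expect_lt(kkt_violation(sys, f2), 1e-6)
  f3 <- solve_regularized(sys, 0.01, lambda_eta = 0.05)
  expect_lt(kkt_violation(sys, f3), 1e-6)
})

test_that("objective decreases monotonically across sweeps and matches recomputation", {
  sys <- random_amplified_system(seed = 3)
  fit <- solve_regularized(sys, 0.02)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  expect_equal(fit$objective,
               sm_objective(sys, fit$K, fit$eta, 0.02, 0, TRUE),
               tolerance = 1e-8)
})

test_that("large lambda gives full off-diagonal shrinkage", {
  sys <- random_amplified_system(seed = 2)
  fit <- solve_regularized(sys, 10 * max(abs(sys$g)))
  expect_equal(nrow(fit$support), 0L)
})

test_that("the solution path is piecewise linear in lambda on a fixed active set", {
  sys <- random_amplified_system(seed = 4)
  # shrink the interval around a base lambda until the active set is constant
  l1 <- 0.010
  f1 <- solve_regularized(sys, l1, tol = 1e-13)
  width <- 0.2
  for (i in 1:20) {
    l2 <- l1 * (1 + width)
    f2 <- solve_regularized(sys, l2, tol = 1e-13)
    if (identical(sign(unname(f1$K)), sign(unname(f2$K)))) break
    width <- width / 2
  }
  expect_identical(sign(unname(f1$K)), sign(unname(f2$K)))
  fm <- solve_regularized(sys, (l1 + l2) / 2, tol = 1e-13)
  expect_equal(unname(fm$K), unname(f1$K + f2$K) / 2, tolerance = 1e-7)
  expect_equal(fm$eta, (f1$eta + f2$eta) / 2, tolerance = 1e-7)
})

test_that("profiled solve equals the joint solve with unpenalized eta", {
  sys <- random_amplified_system(n = 30, m = 5, seed = 10)
  for (lam in c(0.005, 0.05)) {
    pf <- solve_profiled(sys, lam, tol = 1e-10)
    fr <- solve_regularized(sys, lam, lambda_eta = 0, tol = 1e-10)
    expect_lt(max(abs(pf$K - fr$K)), 1e-5)
    expect_lt(max(abs(pf$eta - fr$eta)), 1e-5)
  }
  # full shrinkage: eta falls back to the closed-form back-substitution
  big <- solve_profiled(sys, 10 * max(abs(sys$g)))
  expect_equal(nrow(big$support), 0L)
  # centered systems cannot be profiled
  expect_error(solve_profiled(random_amplified_system(centered = TRUE), 0.1),
               "non-centered")
})

test_that("warm-started paths match cold fits and end sparse at lambda_max", {
  sys <- random_amplified_system(n = 25, m = 5, seed = 12)
  p <- fit_path(sys, n_lambda = 8, lambda_min_ratio = 0.01)
  expect_equal(p$edge_counts[1], 0L)
  expect_true(all(diff(p$lambdas) < 0))
  for (i in c(2, 5, 8)) {
    cold <- solve_regularized(sys, p$lambdas[i], tol = 1e-8)
    expect_lt(max(abs(cold$K - p$fits[[i]]$K)), 1e-6)
  }
  # degenerate grid collapses to identical fits
  pc <- fit_path(sys, n_lambda = 3, lambda_min_ratio = 1)
  expect_equal(pc$fits[[1]]$K, pc$fits[[3]]$K)
  expect_error(fit_path(sys, n_lambda = 1), "at least 2")
})

test_that("without amplification the n << m loss is unbounded below", {
  x <- random_positive_data(2, 5, seed = 21)
  spec <- model_spec("trunc_gaussian", centered = TRUE)
  sys <- build_system(x, "min(x,3)", spec)
  esc <- kernel_escape_direction(sys)
  expect_false(is.null(esc))
  expect_gt(abs(esc$g_dot_nu), 1e-8)
  # moving along the kernel direction drives the lambda = 0 loss down linearly
  K0 <- matrix(0, 5, 5)
  obj_at <- function(t) {
    K <- K0; K[, esc$block] <- K[, esc$block] + t * sign(esc$g_dot_nu) * esc$nu
    sm_objective(sys, K, lambda_K = 0)
  }
  expect_lt(obj_at(1e3), obj_at(1) - 100)
  # any delta > 1 restores a unique minimizer
  amp <- amplify(sys, delta = 1.5)
  f1 <- solve_regularized(amp, 0, tol = 1e-10)
  f2 <- solve_regularized(amp, 0, tol = 1e-10,
                          init = list(K = diag(5) * 3))
  expect_lt(max(abs(f1$K - f2$K)), 1e-6)
})

test_that("h = x^2 with a = b = 1 recovers the classical x^2-weighted loss", {
  # independent direct coding of the x^2-weighted score matching system
  x <- random_positive_data(8, 3, seed = 30)
  n <- nrow(x); m <- ncol(x)
  sys <- build_system(x, "x^2", model_spec("trunc_gaussian"))
  for (j in 1:m) {
    w <- x[, j]^2
    G11 <- t(x) %*% (w * x) / n
    G12 <- -colSums(w * x) / n
    G22 <- mean(w)
    gj <- colSums(2 * x[, j] * x) / n
    gj[j] <- gj[j] + mean(w)
    expect_lt(max(abs(sys$blocks[, , j] -
                        rbind(cbind(G11, G12), c(G12, G22)))), 1e-10)
    expect_lt(max(abs(sys$g[, j] - c(gj, -mean(2 * x[, j])))), 1e-10)
  }
})

test_that("support recovery sharpens with n on a 10-variable truncated GGM", {
  spec <- model_spec("trunc_gaussian", centered = TRUE)
  truth <- make_k0_block(10, pi = 0.5, n_blocks = 2, seed = 77)
  key <- function(s) (s[, 1] - 1) * 10 + s[, 2]
  ns <- c(1000, 8000)
  f1 <- err <- rep(NA_real_, length(ns))
  for (i in seq_along(ns)) {
    x <- sample_truncated_normal(ns[i], truth, seed = 78, thin = 5)
    sys <- amplify(build_system(x, "min(x,3)", spec), delta = 1.02)
    # oracle lambda on the sqrt(log m / n) scale: best constant in a grid
    for (cc in c(0.5, 1, 2, 4)) {
      fit <- solve_regularized(sys, cc * sqrt(log(10) / ns[i]),
                               penalize_diag = FALSE)
      tp <- sum(key(fit$support) %in% key(truth$support))
      prec <- if (nrow(fit$support)) tp / nrow(fit$support) else 0
      rec <- tp / nrow(truth$support)
      f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      if (is.na(f1[i]) || f > f1[i]) {
        f1[i] <- f
        err[i] <- max(abs(fit$K - truth$K0))
      }
    }
  }
  expect_gt(f1[2], 0.9)
  expect_gte(f1[2], f1[1] - 1e-9)
  expect_lt(err[2], err[1])
})
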