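test_that("parameter validation follows the integrability conditions", {
  tg <- model_spec("trunc_gaussian")
  expect_true(validate_parameters(tg, diag(2), c(0, 0))$ok)
  gm <- model_spec("gamma")
  expect_false(validate_parameters(gm, diag(2), c(-1.5, 0))$ok)
  bad <- model_spec("general", a = 1, b = 3)
  expect_false(validate_parameters(bad, diag(2), c(1, 1))$ok)
  # not PD but non-negative with positive diagonal: flagged unverified
  K <- matrix(c(1, 2, 2, 1), 2)
  r <- validate_parameters(tg, K, c(0, 0))
  expect_false(r$ok)
  expect_match(r$report, "unverified")
  expect_error(validate_parameters(tg, diag(2), c(0, 0, 0)), "dimension")
})

test_that("truncated-GGM blocks match the hand-evaluated single-row example", {
  sys <- build_system(matrix(c(1, 2), 1, 2), h_power(2),
                      model_spec("trunc_gaussian", centered = TRUE))
  expect_equal(sys$blocks[, , 1], matrix(c(1, 2, 2, 4), 2), tolerance = 1e-12)
  expect_equal(sys$g[, 1], c(3, 4), tolerance = 1e-12)
  sys2 <- build_system(matrix(c(1, 1), 1, 2), h_constant(),
                       model_spec("trunc_gaussian", centered = TRUE))
  expect_equal(sys2$blocks[, , 1], matrix(1, 2, 2))
  expect_equal(sys2$blocks[, , 2], matrix(1, 2, 2))
})

test_that("generic a/b path reproduces an independent coding of the a=b=1 blocks", {
  x <- random_positive_data(7, 4, seed = 3)
  for (h in list("min(x,3)", "x^2", "mcp(1,10)")) {
    sys <- build_system(x, h, model_spec("trunc_gaussian"))
    oracle <- tggm_blocks_direct(x, h)
    expect_lt(max(abs(sys$blocks - oracle$blocks)), 1e-10)
    expect_lt(max(abs(sys$g - oracle$g)), 1e-10)
  }
})

test_that("exponential and gamma systems share their K parts (a = 1/2)", {
  x <- random_positive_data(9, 3, seed = 4)
  se <- build_system(x, "min(x^1.5,2)", model_spec("exponential"))
  sg <- build_system(x, "min(x^1.5,2)", model_spec("gamma"))
  m <- 3
  expect_lt(max(abs(se$blocks[1:m, 1:m, ] - sg$blocks[1:m, 1:m, ])), 1e-12)
  expect_lt(max(abs(se$g[1:m, ] - sg$g[1:m, ])), 1e-12)
  # but their eta parts differ (b = 1/2 vs b = 0)
  expect_gt(max(abs(se$g[m + 1, ] - sg$g[m + 1, ])), 1e-6)
})

test_that("unamplified blocks are symmetric PSD Gram matrices", {
  specs <- list(model_spec("trunc_gaussian"),
                model_spec("exponential", centered = TRUE),
                model_spec("gamma"),
                model_spec("general", a = 1.5, b = 0.5))
  for (s in specs) {
    x <- random_positive_data(6, 4, seed = 8)
    sys <- build_system(x, "min(x,2)", s)
    for (j in 1:4) {
      B <- sys$blocks[, , j]
      expect_equal(B, t(B))
      expect_true(all(diag(B) >= 0))
      expect_gt(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values),
                -1e-10)
    }
  }
})

test_that("the system is homogeneous in h and the estimator invariant to c*h", {
  x <- random_positive_data(6, 3, seed = 9)
  # MCP is homogeneous in pen_lambda at fixed gamma*lambda:
  # MCP(x; c*l, g/c) = c * MCP(x; l, g), giving an exact c*h within the family
  s1 <- build_system(x, h_mcp(1, 8), model_spec("trunc_gaussian"))
  s4 <- build_system(x, h_mcp(4, 2), model_spec("trunc_gaussian"))
  expect_lt(max(abs(s4$blocks - 4 * s1$blocks)), 1e-10)
  expect_lt(max(abs(s4$g - 4 * s1$g)), 1e-10)
  expect_equal(closed_form(amplify(s4, delta = 1.2))$K,
               closed_form(amplify(s1, delta = 1.2))$K, tolerance = 1e-8)
})

test_that("zeros with negative required exponents raise a named domain error", {
  x <- matrix(c(0.5, 0, 1, 2), 2, 2)
  expect_error(build_system(x, "x", model_spec("gamma")), "row 2, column 1")
  # a = b = 1 centered never needs a negative power: zeros are fine
  expect_silent(build_system(x, "x",
                             model_spec("trunc_gaussian", centered = TRUE)))
})

test_that("gaussian R^m system solves the identity example and refuses rank-deficiency", {
  gs <- build_system_gaussian(diag(2))
  expect_equal(gs$blocks[, , 1], 0.5 * diag(2))
  expect_equal(unname(closed_form(gs)$K), 2 * diag(2))
  one_row <- build_system_gaussian(matrix(c(1, 2), 1, 2))
  expect_error(closed_form(one_row), "singular")
  expect_no_error(closed_form(amplify(one_row, delta = 1.5)))
})

test_that("generic callback builder agrees with the power-model fast path", {
  x <- random_positive_data(3, 2, seed = 5)
  m <- 2; side <- m + 1; r <- side * m
  a <- 1; b <- 1
  # column-decoupled sufficient statistics of the pairwise model
  t_grad <- function(xr, j) {
    v <- numeric(r)
    v[(j - 1) * side + seq_len(m)] <- -xr[j]^(a - 1) * xr^a
    v[(j - 1) * side + side] <- xr[j]^(b - 1)
    v
  }
  t_hess <- function(xr, j) {
    v <- numeric(r)
    v[(j - 1) * side + seq_len(m)] <- -(a - 1) * xr[j]^(a - 2) * xr^a
    v[(j - 1) * side + j] <- -(2 * a - 1) * xr[j]^(2 * a - 2)
    v[(j - 1) * side + side] <- (b - 1) * xr[j]^(b - 2)
    v
  }
  gen <- build_system_generic(x, "min(x,3)", r, t_grad, t_hess)
  sys <- build_system(x, "min(x,3)", model_spec("trunc_gaussian"))
  for (j in 1:m) {
    idx <- (j - 1) * side + seq_len(side)
    expect_lt(max(abs(gen$Gamma[idx, idx] - sys$blocks[, , j])), 1e-10)
    expect_lt(max(abs(gen$g[idx] - sys$g[, j])), 1e-10)
  }
  # blocks do not couple across j
  expect_lt(max(abs(gen$Gamma[1:side, side + seq_len(side)])), 1e-12)
})

test_that("amplification touches only the K-diagonal and preserves limits", {
  sys <- build_system(random_positive_data(6, 3, seed = 2), "x",
                      model_spec("trunc_gaussian"))
  a15 <- amplify(sys, delta = 1.5)
  expect_equal(a15$amplifier[, 2], 0.5 * diag(a15$blocks[, , 2])[1:3])
  expect_identical(a15$blocks, sys$blocks) # blocks untouched, kept separate
  expect_error(amplify(a15, delta = 1.2), "already")
  expect_error(amplify(sys, delta = 0.9), "delta > 1")
  tiny <- amplify(sys, delta = 1 + 1e-12)
  expect_lt(max(abs(tiny$amplifier)), 1e-10)
  gam <- amplify(sys, gamma = c(1, 2, 3))
  expect_equal(gam$amplifier[, 1], c(1, 2, 3))
})

test_that("multiplier bound evaluates correctly at the benchmark sizes", {
  expect_equal(round(multiplier_bound(80, 100), 4), 1.8647)
  expect_equal(round(multiplier_bound(1000, 100), 4), 1.6438)
  expect_equal(multiplier_bound(1000, 100, "medium"), 1.2310,
               tolerance = 1e-4)
  expect_error(multiplier_bound(100, 1), "m >= 2")
})

test_that("column scaling is idempotent and recorded", {
  x <- cbind(c(3, 4), c(1, 1))
  sc <- scale_columns(x)
  expect_equal(sc$x[, 1], c(0.6, 0.8))
  expect_equal(sc$scales[1], 5)
  again <- scale_columns(sc$x)
  expect_equal(again$x, sc$x, tolerance = 1e-12)
  expect_error(scale_columns(cbind(c(1, 1), c(0, 0))), "zero")
})
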