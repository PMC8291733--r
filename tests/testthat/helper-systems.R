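# shared fixtures: small random data sets and systems, built in code

random_positive_data <- function(n, m, seed = 1, offset = 1) {
  set.seed(seed)
  matrix(abs(rnorm(n * m, offset, 0.5)) + 0.05, n, m)
}

random_amplified_system <- function(n = 20, m = 5, seed = 1, h = "min(x,3)",
                                    centered = FALSE, delta = 1.5) {
  x <- random_positive_data(n, m, seed)
  spec <- model_spec("trunc_gaussian", centered = centered)
  amplify(build_system(x, h, spec), delta = delta)
}

# independent direct coding of the truncated-GGM (a = b = 1) blocks,
# straight from the per-block formulas: used as the oracle against
# build_system()'s generic power-model path
tggm_blocks_direct <- function(x, h) {
  h <- parse_h(h)
  n <- nrow(x); m <- ncol(x)
  blocks <- array(0, dim = c(m + 1, m + 1, m))
  g <- matrix(0, m + 1, m)
  for (j in seq_len(m)) {
    hj <- h_evaluate(h, x[, j])
    hpj <- h_derivative(h, x[, j])
    G11 <- t(x) %*% (hj * x) / n
    G12 <- -colSums(hj * x) / n
    G22 <- mean(hj)
    blocks[, , j] <- rbind(cbind(G11, G12), c(G12, G22))
    gj <- colSums(hpj * x) / n
    gj[j] <- gj[j] + mean(hj)
    g[, j] <- c(gj, -mean(hpj))
  }
  list(blocks = blocks, g = g)
}
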