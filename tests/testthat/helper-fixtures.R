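# Small in-code fixtures shared across test files.

# Gaussian expression matrix with one planted two-level factor.
planted_matrix <- function(m = 30, n = 400, frac = 0.3, effect_sd = 5,
                           seed = 1) {
  set.seed(seed)
  z <- rep(c(0, 1), each = m / 2)
  eff <- numeric(n)
  idx <- sample.int(n, round(frac * n))
  eff[idx] <- rnorm(length(idx)) * effect_sd
  Y <- matrix(rnorm(m * n), m, n) + outer(z, eff)
  dimnames(Y) <- list(paste0("cell_", seq_len(m)), paste0("gene_", seq_len(n)))
  list(Y = Y, truth = z, affected = idx, effects = eff)
}

# Tiny count matrix with IDs for I/O tests.
toy_counts <- function() {
  m <- matrix(c(0, 6, 7, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  storage.mode(m) <- "double"
  m
}
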