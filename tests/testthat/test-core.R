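test_that("residualize matches per-gene OLS and is exact on spanned columns", {
  set.seed(21)
  Y <- matrix(rnorm(6 * 4), 6, 4)
  X <- cbind(1, rnorm(6))
  Yp <- residualize(Y, X)
  # independent oracle: lm residuals gene by gene
  for (g in 1:4) {
    expect_equal(unname(Yp[, g]), unname(resid(lm(Y[, g] ~ X - 1))),
                 tolerance = 1e-10)
  }
  # orthogonality to span(X)
  expect_lt(max(abs(crossprod(X, Yp))), 1e-8)
  # intercept-only design is column centering
  Yc <- residualize(Y, matrix(1, 6, 1))
  expect_equal(Yc, sweep(Y, 2, colMeans(Y)), tolerance = 1e-12)
  # columns already in span(X) vanish
  Yspan <- X %*% matrix(rnorm(2 * 3), 2, 3)
  expect_lt(max(abs(residualize(Yspan, X))), 1e-8)
  expect_error(residualize(Y, X[1:5, ]), "row")
})

test_that("residuals of genes on a design with intercept have mean zero", {
  set.seed(22)
  Y <- matrix(rnorm(10 * 7), 10, 7)
  X <- build_design(data.frame(g = rep(c("A", "B"), 5), x = rnorm(10)))
  expect_lt(max(abs(colMeans(residualize(Y, X)))), 1e-10)
})

test_that("first_pc agrees with an independent SVD and handles rank-1 input", {
  u <- c(3, -1, 2, 0.5); u <- u / sqrt(sum(u^2))
  v <- rnorm(9)
  M <- outer(u, v)
  fp <- first_pc(M)
  expect_equal(abs(sum(fp$pc1 * u)), 1, tolerance = 1e-10)
  expect_gt(fp$pc1[which.max(abs(fp$pc1))], 0)  # sign convention
  expect_equal(fp$share, 1, tolerance = 1e-12)

  set.seed(23)
  A <- matrix(rnorm(5 * 8), 5, 8)
  fp2 <- first_pc(A)
  sv <- svd(A)  # independent route (LAPACK dgesdd on the rectangle)
  expect_gt(abs(sum(fp2$pc1 * sv$u[, 1])), 1 - 1e-8)
  expect_equal(fp2$d, sv$d, tolerance = 1e-8)
  # partial mode with num_sv_permtest >= min(m, n) is identical
  fp3 <- first_pc(A, svd_mode = "partial", num_sv_permtest = 10)
  expect_equal(fp3$pc1, fp2$pc1)
  expect_equal(fp3$share, fp2$share)

  expect_error(first_pc(matrix(0, 3, 3)), "degenerate")
})

test_that("gene_r2 equals simple-regression R-squared with degenerate columns at 0", {
  set.seed(24)
  m <- 12
  pc <- rnorm(m)
  Y <- cbind(pc, rnorm(m), rep(2, m), 3 * pc + rnorm(m, sd = 0.1))
  r2 <- unname(gene_r2(Y, pc))
  expect_equal(r2[1], 1, tolerance = 1e-10)
  expect_equal(r2[3], 0)
  for (g in c(2, 4)) {
    expect_equal(r2[g], summary(lm(Y[, g] ~ pc))$r.squared, tolerance = 1e-10)
  }
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("weighted SV reduces to known cases for degenerate weight patterns", {
  set.seed(25)
  Y <- matrix(rnorm(8 * 6), 8, 6)
  # indicator weight: SV is that centered column, normalized
  w <- c(0, 0, 1, 0, 0, 0)
  sv <- weighted_sv(Y, w, center = TRUE)
  col <- Y[, 3] - mean(Y[, 3])
  expect_equal(abs(cor(sv, col)), 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(sv^2)), 1, tolerance = 1e-10)
  # uniform weights: SV is PC1 of the centered matrix
  svu <- weighted_sv(Y, rep(0.5, 6), center = TRUE)
  pc1 <- prcomp(Y, center = TRUE, scale. = FALSE)$x[, 1]
  expect_equal(abs(cor(svu, pc1)), 1, tolerance = 1e-10)
  expect_error(weighted_sv(Y, rep(0, 6)), "zero")
})

test_that("a strongly planted hidden factor is recovered by the weighted SV", {
  px <- planted_matrix(m = 40, n = 600, frac = 0.3, effect_sd = 5, seed = 31)
  Yp <- residualize(px$Y, matrix(1, 40, 1))
  fp <- first_pc(Yp)
  r2 <- gene_r2(Yp, fp$pc1)
  sv <- weighted_sv(px$Y, r2)
  expect_gt(abs(cor(sv, px$truth)), 0.95)
})

test_that("fits are deterministic and SV scores unit norm with valid SI values", {
  px <- planted_matrix(seed = 32)
  f1 <- iasva(px$Y, known = NULL, num_p = 25, max_sv = 3, seed = 7)
  f2 <- iasva(px$Y, known = NULL, num_p = 25, max_sv = 3, seed = 7)
  expect_identical(f1, f2)
  expect_gte(f1$n_sv, 1)
  expect_equal(unname(sqrt(colSums(f1$sv^2))), rep(1, f1$n_sv),
               tolerance = 1e-8)
  expect_true(all(f1$significance_index <= f1$alpha))
  expect_true(all(f1$significance_index %in% ((0:25) / 25)))
  expect_true(all(f1$gene_r2 >= 0 & f1$gene_r2 <= 1))
})

test_that("with hidden structure orthogonal to the design, the first SV matches residual-PCA PC1", {
  # hidden factor orthogonal to the known two-level factor
  set.seed(33)
  m <- 40; n <- 500
  known <- rep(c(0, 1), each = m / 2)
  hidden <- rep(rep(c(0, 1), each = m / 4), 2)  # balanced within known levels
  expect_equal(cor(known, hidden), 0)
  eff_k <- numeric(n); eff_k[sample(n, 50)] <- rnorm(50) * 3
  eff_h <- numeric(n); eff_h[sample(n, 150)] <- rnorm(150) * 5
  Y <- matrix(rnorm(m * n), m, n) + outer(known, eff_k) + outer(hidden, eff_h)
  fit <- iasva(Y, known, num_p = 30, max_sv = 1, seed = 3)
  pc <- residual_pca_baseline(Y, known, n_sv = 1)
  expect_equal(fit$n_sv, 1L)
  expect_gt(abs(cor(fit$sv[, 1], pc[, 1])), 0.99)
  expect_gt(abs(cor(fit$sv[, 1], hidden)), 0.95)
})

test_that("pure-noise data with intercept-only design yields no surrogate variables for most seeds", {
  hits <- vapply(1:12, function(s) {
    set.seed(s + 100)
    Y <- matrix(rnorm(25 * 300), 25, 300)
    iasva(Y, known = NULL, alpha = 0.05, num_p = 40, max_sv = 1,
          seed = s)$n_sv
  }, numeric(1))
  expect_lte(mean(hits >= 1), 2 / 12)
})

test_that("fast mode honors the variance cutoff contract", {
  px <- planted_matrix(m = 30, n = 400, frac = 0.3, effect_sd = 4, seed = 34)
  ff <- fast_iasva(px$Y, pct_cutoff = 1, max_sv = 5)
  expect_gte(ff$n_sv, 1)
  expect_true(all(ff$var_share >= 1))
  expect_gt(abs(cor(ff$sv[, 1], px$truth)), 0.9)
  # a 100% cutoff only accepts a numerically rank-1 residual
  expect_equal(fast_iasva(px$Y, pct_cutoff = 100, max_sv = 3)$n_sv, 0L)
  rank1 <- outer(seq_len(20) - 10.5, rnorm(50))
  f1 <- fast_iasva(rank1, pct_cutoff = 100, max_sv = 3, center_weighted = FALSE)
  expect_lte(f1$n_sv, 1L)
})

test_that("fit methods expose scores, residuals and printable summaries", {
  px <- planted_matrix(seed = 35)
  fit <- iasva(px$Y, known = NULL, num_p = 25, max_sv = 2, seed = 1)
  expect_identical(coef(fit), fit$sv)
  res <- residuals(fit)
  expect_equal(dim(res), dim(px$Y))
  expect_lt(max(abs(crossprod(cbind(1, fit$sv), res))), 1e-6)
  expect_output(print(fit), "surrogate variables")
  expect_output(print(summary(fit)), "diagnostics")
})
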