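#' Residualize expression on a design matrix
#'
#' Projects each gene (column) of `Y` onto the orthogonal complement of the
#' column span of `X`, using a pseudoinverse so rank-deficient designs are
#' handled without error: `Y' = Y - X X^+ Y`.
#'
#' @param Y Cells x genes numeric matrix (log expression).
#' @param X Design matrix with the same number of rows (intercept first; see
#'   [build_design()]).
#' @return Residual matrix of the same shape as `Y`.
#' @export
residualize <- function(Y, X) {
  if (nrow(Y) != nrow(X)) stop("Y and X row counts differ")
  U <- orthonormal_basis(X)
  Y - U %*% crossprod(U, Y)
}

# Orthonormal basis of span(X); singular values below 1e-10 * largest are
# treated as zero (pseudoinverse convention).
orthonormal_basis <- function(X) {
  s <- svd(X, nv = 0)
  keep <- s$d > 1e-10 * s$d[1]
  s$u[, keep, drop = FALSE]
}

# Deterministic sign convention: flip so the entry of largest magnitude is
# positive (SVD signs are otherwise arbitrary).
fix_sign <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s < 0) -v else v
}

#' First principal component of a residual matrix
#'
#' Left singular vector of the largest singular value, computed through the
#' m x m Gram matrix (exact, and cheap because cells are few relative to
#' genes). Also returns all singular values and the proportion of total
#' variance carried by the first: `lambda_1^2 / sum_k lambda_k^2`.
#'
#' @param Yp Residual matrix (cells x genes), not identically zero.
#' @param num_sv_permtest In `"partial"` mode, number of singular values
#'   retained in the returned spectrum; the variance share always uses the
#'   exact Frobenius denominator, so the two modes agree.
#' @param svd_mode `"full"` or `"partial"`.
#' @return List with `pc1` (unit vector, sign-fixed), `d` (singular values)
#'   and `share` (PC1 variance proportion).
#' @export
first_pc <- function(Yp, svd_mode = c("full", "partial"), num_sv_permtest = 10) {
  svd_mode <- match.arg(svd_mode)
  fro2 <- sum(Yp^2)
  if (fro2 <= .Machine$double.eps * length(Yp)) {
    stop("degenerate residual matrix (all zero); iteration cannot proceed")
  }
  G <- tcrossprod(Yp)
  e <- eigen(G, symmetric = TRUE)
  lam2 <- pmax(e$values, 0)
  d <- sqrt(lam2)
  if (svd_mode == "partial") d <- d[seq_len(min(num_sv_permtest, length(d)))]
  list(pc1 = fix_sign(e$vectors[, 1]), d = d, share = lam2[1] / fro2)
}

#' Per-gene coefficient of determination against a component
#'
#' Squared Pearson correlation between each gene column of the residual
#' matrix and the supplied component — the R-squared of the simple linear
#' regression (with intercept) of that gene on the component. Zero-variance
#' genes map to 0.
#'
#' @param Yp Residual matrix (cells x genes).
#' @param pc1 Per-cell component vector.
#' @return Numeric vector of length `ncol(Yp)` with values in \[0, 1\].
#' @export
gene_r2 <- function(Yp, pc1) {
  if (sum(abs(pc1)) == 0) stop("component vector is zero")
  m <- nrow(Yp)
  p <- pc1 - mean(pc1)
  sp <- sum(p^2)
  cross <- as.vector(crossprod(Yp, p))
  ssy <- colSums(Yp^2) - m * colMeans(Yp)^2
  r2 <- cross^2 / (ssy * sp)
  r2[!is.finite(r2) | ssy <= 1e-12 * max(ssy, 0)] <- 0
  pmin(pmax(r2, 0), 1)
}

#' R-squared-weighted surrogate variable extraction
#'
#' Scales each gene of the *original* log matrix by its R-squared weight
#' (`Y'' = Y W`, `W = diag(R^2)`) and returns the unit-norm first left
#' singular vector of the weighted matrix. Because the weighting is applied
#' to `Y` rather than to the residual, the resulting surrogate variable is
#' free to correlate with known covariates.
#'
#' @param Y Original log-expression matrix (cells x genes).
#' @param r2 Per-gene weights in \[0, 1\], not all zero.
#' @param center Column-center `Y` before weighting (default `TRUE`); the
#'   uncentered variant tracks the grand-mean direction and is provided for
#'   completeness.
#' @return Unit-norm per-cell score vector, sign-fixed.
#' @export
weighted_sv <- function(Y, r2, center = TRUE) {
  if (length(r2) != ncol(Y)) stop("weight length does not match gene count")
  if (all(r2 == 0)) stop("all R-squared weights are zero")
  Yc <- if (center) sweep(Y, 2, colMeans(Y), "-") else Y
  Yw <- Yc * rep(r2, each = nrow(Yc))
  e <- eigen(tcrossprod(Yw), symmetric = TRUE)
  fix_sign(e$vectors[, 1])
}

#' Fit iteratively adjusted surrogate variables
#'
#' The main fitting routine. Each iteration: (1) regress the log matrix on
#' the known design plus previously accepted surrogate variables and take
#' residuals; (2) extract PC1 of the residual; (3) assess PC1 with the
#' permutation significance index ([significance_index()]); (4) if accepted
#' (SI <= `alpha`), compute per-gene R-squared against PC1; (5) weight the
#' original log matrix by those R-squared values; (6) take the first left
#' singular vector of the weighted matrix as the surrogate variable and add
#' it to the design. Iteration stops at the first non-significant PC1, at
#' `max_sv`, or on a degenerate residual.
#'
#' @param Y Cells x genes log-expression matrix (see [log_transform()]).
#' @param known Known covariates: data.frame/matrix/vector per cell, or
#'   `NULL` for intercept only.
#' @param alpha Significance-index acceptance threshold (default 0.05).
#' @param num_p Number of permutations M for the significance index
#'   (default 100).
#' @param max_sv Maximum number of surrogate variables to extract
#'   (default 10).
#' @param permute If `FALSE`, skip the permutation test and extract exactly
#'   `max_sv` surrogate variables (the "no-permutation" mode).
#' @param svd_mode `"full"` or `"partial"` spectrum bookkeeping for the
#'   permutation test; numerically identical here (exact Frobenius
#'   denominator), kept for interface compatibility.
#' @param num_sv_permtest Number of singular values retained in partial mode.
#' @param center_weighted Column-center `Y` before the weighted SVD
#'   (default `TRUE`).
#' @param seed Integer seed controlling the permutation streams; identical
#'   seed and configuration give bit-identical results.
#' @param threads Accepted for interface compatibility; permutation
#'   replicates use independent RNG streams indexed by replicate, so results
#'   are identical for any thread count (execution is serial).
#' @param verbose Print per-iteration diagnostics.
#' @return Object of class `"iasva"`: list with `sv` (cells x k score
#'   matrix, unit columns), `significance_index`, `t_obs`, `var_share`,
#'   `gene_r2` (genes x k), `n_sv`, `iterations` (per-iteration diagnostics
#'   data.frame including the stopping iteration), the configuration, and the
#'   inputs needed by methods.
#' @seealso [fast_iasva()], [find_markers()], [summary.iasva()]
#' @examples
#' ds <- simulate_alternative("moderate", n_genes = 1000, m_cells = 50,
#'                            seed = 1)
#' fit <- iasva(log_transform(ds$counts), ds$known_factor, num_p = 25,
#'              max_sv = 3, seed = 1)
#' fit
#' cor(coef(fit), ds$hidden_factors[[1]])
#' @export
iasva <- function(Y, known = NULL, alpha = 0.05, num_p = 100, max_sv = 10,
                  permute = TRUE, svd_mode = c("full", "partial"),
                  num_sv_permtest = 10, center_weighted = TRUE, seed = 1L,
                  threads = 1L, verbose = FALSE) {
  svd_mode <- match.arg(svd_mode)
  stopifnot(alpha > 0, alpha <= 1, num_p >= 1, max_sv >= 1, threads >= 1)
  Y <- as.matrix(Y)
  X0 <- build_design(known, n = nrow(Y))
  fit_iasva_loop(Y, X0, mode = if (permute) "permutation" else "noperm",
                 alpha = alpha, num_p = num_p, max_sv = max_sv,
                 pct_cutoff = NA_real_, svd_mode = svd_mode,
                 num_sv_permtest = num_sv_permtest,
                 center_weighted = center_weighted, seed = seed,
                 verbose = verbose, call = match.call())
}

#' Fast surrogate variable extraction by variance cutoff
#'
#' Same iteration as [iasva()] but a candidate component is accepted when
#' PC1's share of the current residual variance is at least `pct_cutoff`
#' percent, with no permutation test — the quick screening mode for large
#' data.
#'
#' @inheritParams iasva
#' @param pct_cutoff Minimum percent of residual variance PC1 must explain
#'   (default 1).
#' @return Object of class `"iasva"`; `var_share` records each accepted
#'   component's percent share.
#' @export
fast_iasva <- function(Y, known = NULL, pct_cutoff = 1, max_sv = 10,
                       center_weighted = TRUE, verbose = FALSE) {
  stopifnot(pct_cutoff > 0, pct_cutoff <= 100, max_sv >= 1)
  Y <- as.matrix(Y)
  X0 <- build_design(known, n = nrow(Y))
  fit_iasva_loop(Y, X0, mode = "fast", alpha = NA_real_, num_p = 0L,
                 max_sv = max_sv, pct_cutoff = pct_cutoff, svd_mode = "full",
                 num_sv_permtest = 10, center_weighted = center_weighted,
                 seed = NA_integer_, verbose = verbose, call = match.call())
}

fit_iasva_loop <- function(Y, X0, mode, alpha, num_p, max_sv, pct_cutoff,
                           svd_mode, num_sv_permtest, center_weighted, seed,
                           verbose, call) {
  m <- nrow(Y)
  svs <- matrix(numeric(0), m, 0)
  si <- t_obs <- share <- numeric(0)
  r2_mat <- matrix(numeric(0), ncol(Y), 0)
  diag_rows <- list()
  stop_reason <- "max_sv reached"

  for (it in seq_len(max_sv + as.integer(mode == "permutation" || mode == "fast"))) {
    if (ncol(svs) >= max_sv) break
    X <- cbind(X0, svs)
    U <- orthonormal_basis(X)
    Yp <- Y - U %*% crossprod(U, Y)
    fp <- tryCatch(first_pc(Yp, svd_mode, num_sv_permtest),
                   error = function(e) NULL)
    if (is.null(fp)) {
      stop_reason <- "degenerate residual"
      break
    }
    it_si <- NA_real_
    accepted <- TRUE
    if (mode == "permutation") {
      nulls <- .si_null_stats_cpp(Y, U, num_p, as.double(seed), as.double(it))
      it_si <- mean(nulls >= fp$share)
      accepted <- it_si <= alpha
    } else if (mode == "fast") {
      accepted <- 100 * fp$share >= pct_cutoff
    }
    diag_rows[[it]] <- data.frame(iteration = it, t_obs = fp$share,
                                  significance_index = it_si,
                                  pct_share = 100 * fp$share,
                                  accepted = accepted)
    if (verbose) {
      message(sprintf("iteration %d: T = %.4f, SI = %s, %s", it, fp$share,
                      format(it_si), if (accepted) "accepted" else "stop"))
    }
    if (!accepted) {
      stop_reason <- if (mode == "fast") "share below cutoff" else "non-significant PC1"
      break
    }
    r2 <- gene_r2(Yp, fp$pc1)
    sv <- tryCatch(weighted_sv(Y, r2, center_weighted),
                   error = function(e) NULL)
    if (is.null(sv)) {
      stop_reason <- "zero R-squared weights"
      break
    }
    svs <- cbind(svs, sv)
    si <- c(si, it_si)
    t_obs <- c(t_obs, fp$share)
    share <- c(share, 100 * fp$share)
    r2_mat <- cbind(r2_mat, r2)
  }

  k <- ncol(svs)
  if (k) {
    colnames(svs) <- paste0("SV", seq_len(k))
    rownames(svs) <- rownames(Y)
    colnames(r2_mat) <- paste0("SV", seq_len(k))
    rownames(r2_mat) <- colnames(Y)
  }
  structure(list(
    sv = svs,
    significance_index = si,
    t_obs = t_obs,
    var_share = share,
    gene_r2 = r2_mat,
    n_sv = k,
    iterations = if (length(diag_rows)) do.call(rbind, diag_rows) else NULL,
    stop_reason = stop_reason,
    mode = mode,
    alpha = alpha,
    num_p = num_p,
    pct_cutoff = pct_cutoff,
    svd_mode = svd_mode,
    center_weighted = center_weighted,
    seed = seed,
    Y = Y,
    X = X0,
    call = call
  ), class = "iasva")
}
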