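#' Proportion of residual variance explained by the first singular vector
#'
#' The test statistic of the quasi-inferential procedure:
#' `T = lambda_1^2 / sum_k lambda_k^2`, where `lambda_k` are the singular
#' values of the residual matrix. The denominator is computed as the squared
#' Frobenius norm, which is exact in both full and partial SVD modes.
#'
#' @inheritParams first_pc
#' @return A number in (0, 1\].
#' @export
pc1_variance_share <- function(Yp, svd_mode = c("full", "partial"),
                               num_sv_permtest = 10) {
  first_pc(Yp, svd_mode, num_sv_permtest)$share
}

#' Permutation significance index for the leading residual component
#'
#' Quantifies how unusual the observed PC1 variance share is relative to a
#' permutation null, in the spirit of parallel analysis. The observed
#' statistic is computed from `residualize(Y, X)`. For each of `num_p`
#' replicates, every gene column of the *log matrix* `Y` is independently
#' shuffled across cells, the permuted matrix is re-residualized against
#' `X`, and the null statistic recomputed. The significance index is the
#' fraction of null statistics at least as large as the observed one
#' (non-strict comparison). It is reported as a significance index, not a
#' p-value: the permutation null is only calibrated for the largest
#' eigenvalue and is not adjusted across iterations.
#'
#' @param Y Cells x genes log-expression matrix.
#' @param X Design matrix (intercept included; see [build_design()]).
#' @param num_p Number of permutation replicates M (>= 1).
#' @param seed Integer seed; each replicate draws from an independent stream
#'   derived from `(seed, offset, replicate)`, so results do not depend on
#'   execution order or thread count.
#' @param offset Stream offset, used internally to separate iterations of
#'   the fitting loop (default 1).
#' @param svd_mode,num_sv_permtest Spectrum bookkeeping; see [first_pc()].
#' @param threads Accepted for interface compatibility; execution is serial
#'   and results are thread-count invariant by construction.
#' @return List with `si` (in `{0, 1/M, ..., 1}`), `t_obs`, `null_stats`
#'   (length `num_p`) and `num_p`.
#' @export
significance_index <- function(Y, X, num_p = 100, seed = 1L, offset = 1L,
                               svd_mode = c("full", "partial"),
                               num_sv_permtest = 10, threads = 1L) {
  svd_mode <- match.arg(svd_mode)
  if (num_p < 1) stop("num_p must be >= 1")
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X row counts differ")
  U <- orthonormal_basis(X)
  Yp <- Y - U %*% crossprod(U, Y)
  t_obs <- first_pc(Yp, svd_mode, num_sv_permtest)$share
  null_stats <- as.vector(
    .si_null_stats_cpp(Y, U, as.integer(num_p), as.double(seed),
                       as.double(offset))
  )
  list(si = mean(null_stats >= t_obs), t_obs = t_obs,
       null_stats = null_stats, num_p = num_p)
}

#' Independently permute each column of a matrix
#'
#' The permutation primitive used by the significance index: every column is
#' shuffled across rows with its own random permutation, so each gene's
#' marginal distribution is preserved exactly while cross-gene structure is
#' destroyed. Deterministic given `(seed, offset, rep)`.
#'
#' @param Y Numeric matrix.
#' @param seed,offset,rep Integers selecting the permutation stream.
#' @return Matrix of the same shape with each column permuted.
#' @export
permute_columns <- function(Y, seed = 1L, offset = 1L, rep = 0L) {
  Y <- as.matrix(Y)
  out <- .permute_columns_cpp(Y, as.double(seed), as.double(offset),
                              as.double(rep))
  dimnames(out) <- dimnames(Y)
  out
}
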