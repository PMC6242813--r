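#' Residual-PCA baseline surrogate variables
#'
#' The orthogonality-constrained estimator classical surrogate variable
#' analysis reduces to: residualize the log matrix on the known design once
#' and return the top left singular vectors of the residual. Every returned
#' vector is orthogonal to the span of `X` by construction. With
#' `control_genes` supplied, the SVD is restricted to those gene columns
#' (the supervised variant, mirroring control-gene based methods).
#'
#' @param Y Cells x genes log-expression matrix.
#' @param known Known covariates (see [build_design()]) or a prebuilt design
#'   matrix via `X`.
#' @param n_sv Number of components to return.
#' @param control_genes Optional integer/logical index of genes assumed
#'   unaffected by the factor of interest.
#' @param X Optional design matrix overriding `known`.
#' @return Cells x `n_sv` matrix of unit-norm, sign-fixed score vectors.
#' @export
residual_pca_baseline <- function(Y, known = NULL, n_sv = 2,
                                  control_genes = NULL, X = NULL) {
  Y <- as.matrix(Y)
  if (is.null(X)) X <- build_design(known, n = nrow(Y))
  Yp <- residualize(Y, X)
  if (!is.null(control_genes)) Yp <- Yp[, control_genes, drop = FALSE]
  e <- eigen(tcrossprod(Yp), symmetric = TRUE)
  k <- min(n_sv, ncol(e$vectors))
  out <- vapply(seq_len(k), function(i) fix_sign(e$vectors[, i]),
                numeric(nrow(Y)))
  colnames(out) <- paste0("PC", seq_len(k))
  rownames(out) <- rownames(Y)
  out
}

#' Match estimated surrogate variables to true factors
#'
#' Greedy one-to-one assignment by descending absolute Pearson correlation;
#' true factors left unmatched (fewer estimates than truths) receive
#' `abs_r = 0`.
#'
#' @param true_factors List of per-cell truth vectors.
#' @param estimated_svs Matrix (cells x k) or list of estimated score
#'   vectors; may be empty.
#' @return Data.frame with one row per true factor: `factor`, `sv` (matched
#'   estimate index, `NA` if unmatched) and `abs_r`.
#' @export
match_factors <- function(true_factors, estimated_svs) {
  nf <- length(true_factors)
  if (is.list(estimated_svs)) {
    estimated_svs <- if (length(estimated_svs)) {
      do.call(cbind, estimated_svs)
    } else {
      NULL
    }
  }
  k <- if (is.null(estimated_svs)) 0L else ncol(estimated_svs)
  out <- data.frame(factor = seq_len(nf), sv = NA_integer_, abs_r = 0)
  if (k == 0L || nf == 0L) return(out)
  R <- abs(vapply(seq_len(k), function(j) {
    vapply(true_factors, function(f) {
      r <- suppressWarnings(cor(f, estimated_svs[, j]))
      if (is.finite(r)) r else 0
    }, numeric(1))
  }, numeric(nf)))
  R <- matrix(R, nrow = nf, ncol = k)
  for (step in seq_len(min(nf, k))) {
    best <- which(R == max(R), arr.ind = TRUE)[1, , drop = TRUE]
    i <- best[1]; j <- best[2]
    out$sv[i] <- j
    out$abs_r[i] <- R[i, j]
    R[i, ] <- -1
    R[, j] <- -1
  }
  out
}

bench_child_seed <- function(seed, rep, salt) {
  (as.integer(seed) + 7919L * as.integer(rep) + salt) %% 2147483629L
}

#' Empirical type-I error under the null scenario
#'
#' Simulates null datasets (known factor only), fits the iterative estimator
#' on the log1p counts with the known factor as covariate, and reports the
#' fraction of replicates on which at least one significant surrogate
#' variable is returned.
#'
#' @param n_replicates Number of null simulations.
#' @param n_genes,m_cells Simulated matrix size (defaults 10000 x 50).
#' @param alpha,num_p Significance-index threshold and permutation count
#'   passed to [iasva()] (defaults 0.05 / 50, the benchmark settings).
#' @param seed Root seed; per-replicate seeds are derived from it.
#' @return List with `type1_error`, per-replicate `detections`,
#'   `n_replicates` and `seed`.
#' @export
run_type1 <- function(n_replicates = 200, n_genes = 10000, m_cells = 50,
                      alpha = 0.05, num_p = 50, seed = 1L) {
  detections <- vapply(seq_len(n_replicates), function(r) {
    s <- bench_child_seed(seed, r, 11L)
    ds <- simulate_null(n_genes, m_cells, seed = s)
    fit <- iasva(log_transform(ds$counts), ds$known_factor, alpha = alpha,
                 num_p = num_p, max_sv = 1, seed = s)
    fit$n_sv >= 1
  }, logical(1))
  list(type1_error = mean(detections), detections = detections,
       n_replicates = n_replicates, seed = seed)
}

#' Empirical power and estimation accuracy under the alternative scenario
#'
#' Per replicate: simulate three hidden factors ([simulate_alternative()]),
#' fit the iterative estimator, match significant surrogate variables to the
#' true factors one-to-one ([match_factors()]). A factor counts as detected
#' when its matched significant SV has `abs_r >= detect_threshold`. Power is
#' the per-factor detection fraction; accuracy is the mean matched |r|,
#' reported both with unmatched factors contributing 0 (`accuracy`) and
#' averaged over detected replicates only (`accuracy_detected`).
#'
#' @inheritParams run_type1
#' @param regime Correlation regime of [simulate_alternative()].
#' @param detect_threshold Minimum matched |r| for a detection
#'   (default 0.3).
#' @param max_sv Cap on extracted surrogate variables (default 5).
#' @return List with `power`, `accuracy`, `accuracy_detected` (each length
#'   3), `power_sensitivity` (power recomputed at thresholds 0.2/0.3/0.5),
#'   the per-replicate `abs_r` matrix, realized correlation matrix, and
#'   settings.
#' @export
run_power_accuracy <- function(n_replicates = 200,
                               regime = c("moderate", "weak"),
                               n_genes = 10000, m_cells = 50, alpha = 0.05,
                               num_p = 50, detect_threshold = 0.3,
                               max_sv = 5, seed = 1L) {
  regime <- match.arg(regime)
  nf <- 3L
  abs_r <- matrix(NA_real_, n_replicates, nf)
  detected <- matrix(FALSE, n_replicates, nf)
  realized <- matrix(NA_real_, n_replicates, nf)
  for (r in seq_len(n_replicates)) {
    s <- bench_child_seed(seed, r, 23L)
    ds <- simulate_alternative(regime, n_genes, m_cells, seed = s)
    fit <- iasva(log_transform(ds$counts), ds$known_factor, alpha = alpha,
                 num_p = num_p, max_sv = max_sv, seed = s)
    mm <- match_factors(ds$hidden_factors, fit$sv)
    abs_r[r, ] <- mm$abs_r
    detected[r, ] <- !is.na(mm$sv) & mm$abs_r >= detect_threshold
    realized[r, ] <- ds$realized_cor
  }
  acc_det <- vapply(seq_len(nf), function(i) {
    if (any(detected[, i])) mean(abs_r[detected[, i], i]) else NA_real_
  }, numeric(1))
  sens <- vapply(c(0.2, 0.3, 0.5), function(th) colMeans(abs_r >= th),
                 numeric(nf))
  colnames(sens) <- paste0("thr", c(0.2, 0.3, 0.5))
  list(power = colMeans(detected),
       power_sensitivity = sens,
       accuracy = colMeans(abs_r),
       accuracy_detected = acc_det,
       abs_r = abs_r, detected = detected, realized_cor = realized,
       regime = regime, detect_threshold = detect_threshold,
       n_replicates = n_replicates, seed = seed)
}

#' Accuracy versus known/hidden gene-overlap percentage
#'
#' For each overlap percentage `k`, simulates the overlap scenario and
#' records the best absolute correlation between the single true hidden
#' factor and the estimates from three methods: the iterative estimator, the
#' residual-PCA baseline, and the supervised residual-PCA variant (SVD
#' restricted to genes unaffected by the known factor).
#'
#' @inheritParams run_type1
#' @param k_values Overlap percentages to sweep.
#' @param n_replicates Replicates per `k`.
#' @param n_sv_baseline Components retained by the baselines (default 2).
#' @param max_sv Cap for the iterative estimator (default 3).
#' @return Data.frame with columns `k`, `method`, `mean_abs_r`, and the
#'   per-replicate matrix as `attr(, "replicates")`.
#' @export
run_overlap_sweep <- function(k_values = c(0, 50, 99), n_replicates = 50,
                              n_genes = 10000, m_cells = 50, alpha = 0.05,
                              num_p = 50, n_sv_baseline = 2, max_sv = 3,
                              seed = 1L) {
  methods <- c("iasva", "residual_pca", "supervised_residual_pca")
  rows <- list()
  reps <- list()
  for (k in k_values) {
    rmat <- matrix(NA_real_, n_replicates, length(methods),
                   dimnames = list(NULL, methods))
    for (r in seq_len(n_replicates)) {
      s <- bench_child_seed(seed, r, 37L + as.integer(k))
      ds <- simulate_overlap(k, n_genes, m_cells, seed = s)
      Y <- log_transform(ds$counts)
      truth <- ds$hidden_factors[[1]]
      fit <- iasva(Y, ds$known_factor, alpha = alpha, num_p = num_p,
                   max_sv = max_sv, seed = s)
      rmat[r, "iasva"] <- best_abs_cor(truth, fit$sv)
      pcs <- residual_pca_baseline(Y, ds$known_factor, n_sv = n_sv_baseline)
      rmat[r, "residual_pca"] <- best_abs_cor(truth, pcs)
      ctrl <- setdiff(seq_len(n_genes), ds$known_mask)
      spcs <- residual_pca_baseline(Y, ds$known_factor, n_sv = n_sv_baseline,
                                    control_genes = ctrl)
      rmat[r, "supervised_residual_pca"] <- best_abs_cor(truth, spcs)
    }
    reps[[as.character(k)]] <- rmat
    rows[[as.character(k)]] <- data.frame(k = k, method = methods,
                                          mean_abs_r = colMeans(rmat))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  out
}

best_abs_cor <- function(truth, svs) {
  if (is.null(svs) || NCOL(svs) == 0) return(0)
  svs <- as.matrix(svs)
  best <- max(vapply(seq_len(ncol(svs)), function(j) {
    r <- suppressWarnings(cor(truth, svs[, j]))
    if (is.finite(r)) abs(r) else 0
  }, numeric(1)))
  best
}
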