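#' Default zero-inflated negative binomial gene parameters
#'
#' Draws per-gene ZINB parameters emulating full-length (plate-based)
#' single-cell RNA-seq counts:
#' * gene means `mu` log-normal, `log mu ~ N(1.5, 1.5^2)` truncated to
#'   \[0.1, 1e4\];
#' * dispersion `size` following a fitted mean-dispersion trend,
#'   `log size = -0.4 + 0.5 log mu + N(0, 0.3^2)` — low-expression genes are
#'   strongly over-dispersed, abundant genes less so, as in parameter sets
#'   estimated from real data;
#' * dropout probability decreasing with expression,
#'   `p0 = plogis(a - log mu)`, with the scalar intercept `a` solved once so
#'   the expected baseline zero fraction equals `zero_target` (default
#'   0.70). Dropout concentrated in lowly expressed genes is the empirical
#'   signature of single-cell zeros; a dropout rate flat in expression would
#'   censor even the most abundant genes.
#'
#' Uses the current RNG state; callers seed first.
#'
#' @param n_genes Number of genes.
#' @param zero_target Target overall zero fraction for a baseline matrix.
#' @return List with numeric vectors `mu`, `size`, `p0` and the solved
#'   dropout intercept `a`.
#' @export
sim_zinb_params <- function(n_genes, zero_target = 0.70) {
  mu <- pmin(pmax(exp(rnorm(n_genes, 1.5, 1.5)), 0.1), 1e4)
  size <- exp(-0.4 + 0.5 * log(mu) + rnorm(n_genes, 0, 0.3))
  pnb0 <- (size / (size + mu))^size
  zero_frac <- function(a) {
    p0 <- stats::plogis(a - log(mu))
    mean(p0 + (1 - p0) * pnb0)
  }
  if (zero_frac(-30) > zero_target) {
    a <- -Inf
  } else {
    a <- uniroot(function(a) zero_frac(a) - zero_target, c(-30, 30),
                 tol = 1e-10)$root
  }
  list(mu = mu, size = size, p0 = stats::plogis(a - log(mu)), a = a)
}

# ZINB draw: counts from NB(mu = exp(log_mu), size), then zeroed with
# per-gene dropout probability p0. log_mu is cells x genes.
zinb_draw <- function(log_mu, size, p0) {
  m <- nrow(log_mu)
  n <- ncol(log_mu)
  counts <- matrix(
    rnbinom(m * n, size = rep(size, each = m), mu = exp(as.vector(log_mu))),
    m, n
  )
  drop <- matrix(runif(m * n) < rep(p0, each = m), m, n)
  counts[drop] <- 0L
  dimnames(counts) <- list(paste0("cell_", seq_len(m)),
                           paste0("gene_", seq_len(n)))
  counts
}

# Balanced two-level vector (0/1), first half 0.
balanced_binary <- function(m) {
  rep(c(0, 1), c(ceiling(m / 2), floor(m / 2)))
}

#' Binary vector at a controlled correlation with a base vector
#'
#' Copies `base` and flips labels at random positions, resampling the flip
#' count and positions until the realized Pearson (phi) correlation with
#' `base` lands inside `window` (interval on |r|, inclusive). The realized
#' signed correlation is attached as `attr(, "realized_r")`.
#'
#' @param base Binary (0/1) vector with both levels present.
#' @param window Length-2 interval for the absolute correlation; `c(1, 1)`
#'   returns `base` unchanged.
#' @param max_tries Resampling budget before failing (default 1000).
#' @return Binary vector of the same length with both levels present.
#' @export
correlated_binary <- function(base, window, max_tries = 1000) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (length(unique(base)) < 2) stop("base vector must have both levels")
  m <- length(base)
  if (window[1] >= 1) {
    out <- base
    attr(out, "realized_r") <- 1
    return(out)
  }
  # For a balanced base, flipping k random labels leaves |r| near 1 - 2k/m;
  # sample k over the bracketing range and keep rejecting until the realized
  # value lands inside the window.
  k_lo <- max(0L, floor(m * (1 - window[2]) / 2))
  k_hi <- min(m, ceiling(m * (1 - window[1]) / 2))
  for (i in seq_len(max_tries)) {
    k <- if (k_hi > k_lo) sample(k_lo:k_hi, 1) else k_lo
    cand <- base
    if (k > 0) {
      idx <- sample.int(m, k)
      cand[idx] <- 1 - cand[idx]
    }
    if (length(unique(cand)) < 2) next
    r <- cor(base, cand)
    if (abs(r) >= window[1] && abs(r) <= window[2]) {
      attr(cand, "realized_r") <- r
      return(cand)
    }
  }
  stop("could not realize correlation window [", window[1], ", ", window[2],
       "] in ", max_tries, " tries")
}

# Random balanced binary vector weakly associated with nothing in particular.
random_balanced_binary <- function(m) {
  sample(balanced_binary(m))
}

new_sim_dataset <- function(counts, known, known_mask, known_effects,
                            hidden, hidden_masks, hidden_effects,
                            realized_cor, zinb, seed, scenario, extra = list()) {
  structure(c(list(
    counts = counts,
    known_factor = known,
    known_mask = known_mask,
    known_effects = known_effects,
    hidden_factors = hidden,
    hidden_masks = hidden_masks,
    hidden_effects = hidden_effects,
    realized_cor = realized_cor,
    zinb = zinb,
    seed = seed,
    scenario = scenario
  ), extra), class = "iasva_sim")
}

#' @export
print.iasva_sim <- function(x, ...) {
  cat(sprintf("Simulated scRNA-seq dataset ('%s'): %d cells x %d genes\n",
              x$scenario, nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  zero fraction: %.3f\n", mean(x$counts == 0)))
  cat(sprintf("  hidden factors: %d", length(x$hidden_factors)))
  if (length(x$realized_cor)) {
    cat(sprintf(" (|r| with known factor: %s)",
                paste(sprintf("%.2f", abs(x$realized_cor)), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

# Assemble counts for a known factor plus optional hidden factors. Effects
# act multiplicatively on the NB mean with a symmetric two-level contrast:
# log mu[c, g] = log mu_g + sum_f effect_f[g] * s_f[c], s in {-1, +1}, so
# the log-fold-change between levels of an affected gene is 2 * effect and
# the gene's baseline mean is level-independent. Dropout probabilities are
# unaffected (zeros stay technical).
sim_counts_with_effects <- function(m_cells, zinb, factors, effects) {
  n <- length(zinb$mu)
  log_mu <- matrix(log(zinb$mu), m_cells, n, byrow = TRUE)
  for (i in seq_along(factors)) {
    log_mu <- log_mu + outer(2 * factors[[i]] - 1, effects[[i]])
  }
  zinb_draw(log_mu, zinb$size, zinb$p0)
}

masked_effects <- function(n_genes, mask) {
  eff <- numeric(n_genes)
  eff[mask] <- rnorm(length(mask))
  eff
}

#' Baseline simulated count matrix (no factor effects)
#'
#' Draws a ZINB count matrix with no planted factors — the calibration
#' scenario whose zero fraction should sit near 70%.
#'
#' @param n_genes,m_cells Matrix dimensions (defaults 10000 x 50).
#' @param seed Integer seed.
#' @param zinb Optional ZINB parameter list ([sim_zinb_params()]); drawn
#'   fresh when `NULL`.
#' @return Object of class `"iasva_sim"`.
#' @export
simulate_baseline <- function(n_genes = 10000, m_cells = 50, seed = 1L,
                              zinb = NULL) {
  set.seed(seed)
  if (is.null(zinb)) zinb <- sim_zinb_params(n_genes)
  counts <- sim_counts_with_effects(m_cells, zinb, list(), list())
  new_sim_dataset(counts, known = NULL, known_mask = integer(0),
                  known_effects = numeric(n_genes), hidden = list(),
                  hidden_masks = list(), hidden_effects = list(),
                  realized_cor = numeric(0), zinb = zinb, seed = seed,
                  scenario = "baseline")
}

#' Simulate the null scenario: a known factor, no hidden factors
#'
#' Balanced two-level known factor (e.g. sex) whose N(0,1) effects hit a
#' random `known_fraction` of genes; counts are ZINB with ~70% zeros at
#' baseline. Ground truth (factor vector, affected-gene mask, effect sizes)
#' is recorded.
#'
#' @param n_genes,m_cells Matrix dimensions (defaults 10000 x 50).
#' @param known_fraction Fraction of genes affected by the known factor
#'   (default 0.10).
#' @param seed Integer seed.
#' @param zinb Optional ZINB parameter list.
#' @return Object of class `"iasva_sim"`.
#' @export
simulate_null <- function(n_genes = 10000, m_cells = 50,
                          known_fraction = 0.10, seed = 1L, zinb = NULL) {
  stopifnot(n_genes >= 1, m_cells >= 2, known_fraction > 0,
            known_fraction <= 1)
  set.seed(seed)
  if (is.null(zinb)) zinb <- sim_zinb_params(n_genes)
  known <- balanced_binary(m_cells)
  mask <- sort(sample.int(n_genes, round(known_fraction * n_genes)))
  beta <- masked_effects(n_genes, mask)
  counts <- sim_counts_with_effects(m_cells, zinb, list(known), list(beta))
  new_sim_dataset(counts, known, mask, beta, hidden = list(),
                  hidden_masks = list(), hidden_effects = list(),
                  realized_cor = numeric(0), zinb = zinb, seed = seed,
                  scenario = "null")
}

#' Simulate the alternative scenario: three correlated hidden factors
#'
#' On top of the null design, plants three two-level hidden factors
#' affecting `fractions` (default 30%/20%/10%) of randomly chosen genes with
#' N(0,1) effect sizes. In the `"moderate"` regime each hidden factor is
#' built by label-flipping from the known factor until its |r| with the
#' known factor lies in \[0.3, 0.6\]; in the `"weak"` regime hidden factors
#' are independent balanced vectors accepted when |r| <= 0.3. Realized
#' correlations are recorded.
#'
#' @param regime `"moderate"` or `"weak"` correlation with the known factor.
#' @param n_genes,m_cells Matrix dimensions (defaults 10000 x 50).
#' @param fractions Affected-gene fractions for the hidden factors.
#' @param known_fraction Fraction of genes affected by the known factor.
#' @param seed Integer seed.
#' @param zinb Optional ZINB parameter list.
#' @return Object of class `"iasva_sim"`; `hidden_factors`, `hidden_masks`,
#'   `hidden_effects` and `realized_cor` hold the ground truth.
#' @export
simulate_alternative <- function(regime = c("moderate", "weak"),
                                 n_genes = 10000, m_cells = 50,
                                 fractions = c(0.30, 0.20, 0.10),
                                 known_fraction = 0.10, seed = 1L,
                                 zinb = NULL) {
  regime <- match.arg(regime)
  set.seed(seed)
  if (is.null(zinb)) zinb <- sim_zinb_params(n_genes)
  known <- balanced_binary(m_cells)
  known_mask <- sort(sample.int(n_genes, round(known_fraction * n_genes)))
  beta <- masked_effects(n_genes, known_mask)

  hidden <- vector("list", length(fractions))
  hidden_masks <- vector("list", length(fractions))
  hidden_effects <- vector("list", length(fractions))
  realized <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    if (regime == "moderate") {
      z <- correlated_binary(known, c(0.3, 0.6))
      realized[i] <- attr(z, "realized_r")
    } else {
      repeat {
        z <- random_balanced_binary(m_cells)
        r <- cor(known, z)
        if (abs(r) <= 0.3) break
      }
      realized[i] <- r
    }
    hidden[[i]] <- as.numeric(z)
    hidden_masks[[i]] <- sort(sample.int(n_genes, round(fractions[i] * n_genes)))
    hidden_effects[[i]] <- masked_effects(n_genes, hidden_masks[[i]])
  }
  counts <- sim_counts_with_effects(
    m_cells, zinb, c(list(known), hidden), c(list(beta), hidden_effects)
  )
  new_sim_dataset(counts, known, known_mask, beta, hidden, hidden_masks,
                  hidden_effects, realized, zinb, seed,
                  scenario = paste0("alternative-", regime))
}

#' Simulate the gene-overlap scenario
#'
#' One known factor affecting `known_genes` genes and one hidden factor
#' affecting `hidden_genes` genes, with the two factor vectors highly
#' correlated (target |r| = 0.76) and `k_percent`% of the hidden-affected
#' genes also affected by the known factor. Effect sizes for the two factors
#' are drawn independently from N(0,1), so shared genes carry heterogeneous
#' relative effects.
#'
#' @param k_percent Overlap percentage in `{99, 90, ..., 10, 0}` (any value
#'   in \[0, 100\] is accepted).
#' @param n_genes,m_cells Matrix dimensions (defaults 10000 x 50).
#' @param known_genes,hidden_genes Numbers of affected genes (2000 / 1000).
#' @param target_r Target known-hidden correlation (default 0.76).
#' @param tol Acceptance half-width on the realized correlation
#'   (default 0.05).
#' @param seed Integer seed.
#' @param zinb Optional ZINB parameter list.
#' @return Object of class `"iasva_sim"` with one hidden factor.
#' @export
simulate_overlap <- function(k_percent, n_genes = 10000, m_cells = 50,
                             known_genes = 2000, hidden_genes = 1000,
                             target_r = 0.76, tol = 0.05, seed = 1L,
                             zinb = NULL) {
  stopifnot(k_percent >= 0, k_percent <= 100,
            known_genes + hidden_genes <= n_genes + round(k_percent / 100 * hidden_genes))
  set.seed(seed)
  if (is.null(zinb)) zinb <- sim_zinb_params(n_genes)
  known <- balanced_binary(m_cells)
  z <- correlated_binary(known, c(target_r - tol, target_r + tol))
  realized <- attr(z, "realized_r")

  known_mask <- sort(sample.int(n_genes, known_genes))
  n_shared <- round(k_percent / 100 * hidden_genes)
  shared <- sample(known_mask, n_shared)
  outside <- setdiff(seq_len(n_genes), known_mask)
  own <- sample(outside, hidden_genes - n_shared)
  hidden_mask <- sort(c(shared, own))

  beta <- masked_effects(n_genes, known_mask)
  delta <- masked_effects(n_genes, hidden_mask)
  counts <- sim_counts_with_effects(m_cells, zinb, list(known, as.numeric(z)),
                                    list(beta, delta))
  new_sim_dataset(counts, known, known_mask, beta,
                  hidden = list(as.numeric(z)),
                  hidden_masks = list(hidden_mask),
                  hidden_effects = list(delta),
                  realized_cor = realized, zinb = zinb, seed = seed,
                  scenario = sprintf("overlap-k%g", k_percent),
                  extra = list(k_percent = k_percent))
}
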