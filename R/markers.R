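#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up false-discovery-rate adjustment, with input validation.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Marker genes associated with surrogate variables
#'
#' For each supplied surrogate variable, fits the simple linear regression
#' (with intercept) of every gene's log expression on the SV scores and
#' reports the coefficient of determination, the F-test p-value of the slope
#' and its BH q-value (adjusted across all genes, per SV). A gene is selected
#' when `q < fdr_cutoff` and `R^2 > r2_cutoff` for *any* supplied SV; the
#' association is computed on the expression matrix itself, not on
#' residuals, so reported R-squared values describe the gene/SV relationship
#' directly. With `joint = TRUE` a single multiple regression on all SVs is
#' used instead (overall F-test).
#'
#' @param Y Cells x genes log-expression matrix.
#' @param svs An `"iasva"` fit, a cells x k score matrix, or a single score
#'   vector.
#' @param which Indices of the SVs to test (default all).
#' @param fdr_cutoff BH q-value threshold (default 0.05).
#' @param r2_cutoff R-squared threshold (default 0.3).
#' @param joint Test all selected SVs jointly in one multiple regression.
#' @return Data.frame with one row per gene and SV: `gene_id`, `sv`, `r2`,
#'   `p_value`, `q_value`, `selected`. The union of selected gene IDs is
#'   attached as `attr(, "selected_genes")`, and the thresholds as
#'   attributes `fdr_cutoff` / `r2_cutoff`.
#' @examples
#' set.seed(1)
#' sv <- rnorm(40)
#' Y <- cbind(marker = 2 * sv + rnorm(40, sd = 0.5),
#'            noise = rnorm(40))
#' find_markers(Y, sv)
#' @export
find_markers <- function(Y, svs, which = NULL, fdr_cutoff = 0.05,
                         r2_cutoff = 0.3, joint = FALSE) {
  Y <- as.matrix(Y)
  if (inherits(svs, "iasva")) svs <- svs$sv
  svs <- as.matrix(svs)
  if (nrow(svs) != nrow(Y)) stop("SV scores do not align with cells")
  if (ncol(svs) == 0) stop("no surrogate variables supplied")
  if (is.null(colnames(svs))) colnames(svs) <- paste0("SV", seq_len(ncol(svs)))
  if (!is.null(which)) svs <- svs[, which, drop = FALSE]
  m <- nrow(Y)
  genes <- colnames(Y)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(ncol(Y)))

  if (joint) {
    X <- build_design(NULL, n = m, svs = svs)
    k <- ncol(X) - 1L
    Yp <- residualize(Y, X)
    sse <- colSums(Yp^2)
    sst <- colSums(Y^2) - m * colMeans(Y)^2
    r2 <- 1 - sse / sst
    r2[!is.finite(r2) | sst <= 0] <- 0
    r2 <- pmin(pmax(r2, 0), 1)
    fstat <- (r2 / k) / ((1 - r2) / (m - k - 1))
    p <- pf(fstat, k, m - k - 1, lower.tail = FALSE)
    p[sst <= 0 | !is.finite(p)] <- 1
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    q <- bh_adjust(p)
    res <- data.frame(gene_id = genes, sv = "joint", r2 = r2, p_value = p,
                      q_value = q,
                      selected = q < fdr_cutoff & r2 > r2_cutoff,
                      row.names = NULL)
  } else {
    res <- do.call(rbind, lapply(colnames(svs), function(nm) {
      r2 <- gene_r2(Y, svs[, nm])
      fstat <- (m - 2) * r2 / (1 - r2)
      p <- pf(fstat, 1, m - 2, lower.tail = FALSE)
      p[r2 >= 1] <- .Machine$double.xmin
      p[!is.finite(p)] <- 1
      p <- pmin(pmax(p, .Machine$double.xmin), 1)
      q <- bh_adjust(p)
      data.frame(gene_id = genes, sv = nm, r2 = r2, p_value = p, q_value = q,
                 selected = q < fdr_cutoff & r2 > r2_cutoff, row.names = NULL)
    }))
  }
  attr(res, "selected_genes") <- unique(res$gene_id[res$selected])
  attr(res, "fdr_cutoff") <- fdr_cutoff
  attr(res, "r2_cutoff") <- r2_cutoff
  res
}
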