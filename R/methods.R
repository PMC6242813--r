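#' @export
print.iasva <- function(x, ...) {
  cat("Iteratively adjusted surrogate variable fit\n")
  cat(sprintf("  cells: %d, genes: %d\n", nrow(x$Y), ncol(x$Y)))
  cat(sprintf("  mode: %s", x$mode))
  if (x$mode == "permutation") {
    cat(sprintf(" (alpha = %g, %d permutations)", x$alpha, x$num_p))
  } else if (x$mode == "fast") {
    cat(sprintf(" (variance cutoff = %g%%)", x$pct_cutoff))
  }
  cat("\n")
  cat(sprintf("  surrogate variables: %d (stopped: %s)\n", x$n_sv, x$stop_reason))
  if (x$n_sv) {
    tab <- data.frame(
      t_obs = signif(x$t_obs, 4),
      pct_var = signif(x$var_share, 4),
      SI = x$significance_index,
      row.names = colnames(x$sv)
    )
    print(tab)
  }
  invisible(x)
}

#' Summarize a surrogate variable fit
#'
#' @param object An `"iasva"` fit.
#' @param r2_cutoff Per-SV count of genes with R-squared above this value is
#'   reported (default 0.3).
#' @param ... Unused.
#' @return Object of class `"summary.iasva"`.
#' @export
summary.iasva <- function(object, r2_cutoff = 0.3, ...) {
  genes_above <- if (object$n_sv) {
    colSums(object$gene_r2 > r2_cutoff)
  } else {
    integer(0)
  }
  structure(list(
    n_sv = object$n_sv,
    mode = object$mode,
    stop_reason = object$stop_reason,
    iterations = object$iterations,
    genes_above = genes_above,
    r2_cutoff = r2_cutoff,
    dim = dim(object$Y)
  ), class = "summary.iasva")
}

#' @export
print.summary.iasva <- function(x, ...) {
  cat(sprintf("iasva fit on %d cells x %d genes (%s mode)\n",
              x$dim[1], x$dim[2], x$mode))
  cat(sprintf("%d surrogate variable(s); stopped: %s\n", x$n_sv, x$stop_reason))
  if (!is.null(x$iterations)) {
    cat("\nPer-iteration diagnostics:\n")
    print(x$iterations, row.names = FALSE)
  }
  if (length(x$genes_above)) {
    cat(sprintf("\nGenes with R^2 > %g per SV:\n", x$r2_cutoff))
    print(x$genes_above)
  }
  invisible(x)
}

#' Extract surrogate variable scores
#'
#' @param object An `"iasva"` fit.
#' @param ... Unused.
#' @return Cells x k matrix of unit-norm surrogate variable scores.
#' @export
coef.iasva <- function(object, ...) {
  object$sv
}

#' Residuals of the expression matrix after known factors and surrogate
#' variables
#'
#' @param object An `"iasva"` fit.
#' @param include_svs Remove the fitted surrogate variables along with the
#'   known design (default `TRUE`).
#' @param ... Unused.
#' @return Cells x genes residual matrix.
#' @export
residuals.iasva <- function(object, include_svs = TRUE, ...) {
  X <- if (include_svs && object$n_sv) cbind(object$X, object$sv) else object$X
  residualize(object$Y, X)
}

#' Plot surrogate variable scores
#'
#' Scatterplot of two surrogate variables (or index plot if only one),
#' optionally colored by a per-cell grouping.
#'
#' @param x An `"iasva"` fit.
#' @param which Indices of the two SVs to plot (default `c(1, 2)`).
#' @param color Optional per-cell factor used for point colors.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.iasva <- function(x, which = c(1, 2), color = NULL, ...) {
  if (x$n_sv == 0) stop("no surrogate variables to plot")
  col <- if (is.null(color)) "black" else as.integer(factor(color)) + 1L
  if (x$n_sv == 1 || length(which) == 1) {
    graphics::plot(x$sv[, which[1]], ylab = colnames(x$sv)[which[1]],
                   xlab = "cell", col = col, pch = 19, ...)
  } else {
    graphics::plot(x$sv[, which[1]], x$sv[, which[2]],
                   xlab = colnames(x$sv)[which[1]],
                   ylab = colnames(x$sv)[which[2]], col = col, pch = 19, ...)
  }
  invisible(x)
}
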