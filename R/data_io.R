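#' Read a single-cell count matrix
#'
#' Reads raw counts either from a Matrix Market triplet file with companion
#' one-column gene/cell ID files, or from a delimited dense table with a
#' header row and a leading ID column. The returned matrix is always oriented
#' cells x genes (rows = cells) regardless of the on-disk layout.
#'
#' @param path Path to a `.mtx` Matrix Market file or a delimited table
#'   (TSV/CSV decided by extension, or `sep`).
#' @param layout On-disk orientation: `"cells-by-genes"` or
#'   `"genes-by-cells"`.
#' @param gene_file,cell_file For Matrix Market input, paths to one-ID-per-line
#'   text files. Defaults to `<path>.genes` / `<path>.cells` next to the
#'   matrix file.
#' @param sep Field separator for delimited input; guessed from the file
#'   extension when `NULL` (`,` for `.csv`, tab otherwise).
#' @return Integer matrix, cells x genes, with unique row (cell) and column
#'   (gene) names.
#' @export
read_counts <- function(path,
                        layout = c("cells-by-genes", "genes-by-cells"),
                        gene_file = NULL, cell_file = NULL, sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(gene_file)) gene_file <- paste0(path, ".genes")
    if (is.null(cell_file)) cell_file <- paste0(path, ".cells")
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (layout == "genes-by-cells") m <- t(m)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop("ID file lengths do not match matrix dimensions")
    }
    dimnames(m) <- list(cells, genes)
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                      check.names = FALSE)
    m <- as.matrix(tab)
    if (layout == "genes-by-cells") m <- t(m)
  }
  validate_counts(m)
}

#' Write a count matrix as Matrix Market plus ID files
#'
#' Companion to [read_counts()]: writes `<path>` (`.mtx`), `<path>.genes` and
#' `<path>.cells` in the cells x genes orientation.
#'
#' @param counts Cells x genes count matrix with dimnames.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(colnames(counts), paste0(path, ".genes"))
  writeLines(rownames(counts), paste0(path, ".cells"))
  invisible(path)
}

validate_counts <- function(m) {
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("counts contain missing or non-finite values")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(m != round(m))) stop("counts must be integral")
  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("gene_", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate cell IDs")
  if (anyDuplicated(colnames(m))) stop("duplicate gene IDs")
  m
}

#' Filter lowly expressed genes
#'
#' Retains genes observed above `min_count` reads (strict inequality) in at
#' least `min_cells` cells — the usual expression filter applied before
#' surrogate variable analysis.
#'
#' @param counts Cells x genes count matrix.
#' @param min_count Count a cell must *exceed* for the gene to be considered
#'   observed there (default 5).
#' @param min_cells Minimum number of such cells (default 3).
#' @return The filtered count matrix (possibly with zero columns, with a
#'   warning).
#' @export
filter_genes <- function(counts, min_count = 5, min_cells = 3) {
  stopifnot(min_count >= 0, min_cells >= 1)
  keep <- colSums(counts > min_count) >= min_cells
  if (!any(keep)) warning("all genes removed by expression filter")
  counts[, keep, drop = FALSE]
}

#' Median-library-size normalization
#'
#' Divides each cell by its total count and rescales by the median library
#' size, so every cell sums to the median total. Within-cell proportions are
#' preserved exactly.
#'
#' @param counts Cells x genes count matrix (every cell total must be > 0).
#' @return Real-valued matrix of normalized counts, same shape and dimnames.
#' @export
normalize_median_library <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop("cell(s) with zero total counts: ",
         paste(rownames(counts)[totals <= 0], collapse = ", "))
  }
  counts * (median(totals) / totals)
}

#' Log-transform expression values
#'
#' Applies `log_e(1 + x)` entry-wise; zeros map to zero.
#'
#' @param x Non-negative matrix (raw or normalized counts).
#' @return Matrix of the same shape.
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stop("log_transform requires non-negative entries")
  log1p(x)
}

#' Geometric library size
#'
#' Per-cell sum of `log_e(1 + count)` over genes — the dominant technical
#' covariate in single-cell data, typically supplied as a known factor.
#' Computed on raw counts.
#'
#' @param counts Cells x genes count matrix.
#' @return Named numeric vector, one value per cell.
#' @export
geometric_library_size <- function(counts) {
  rowSums(log1p(counts))
}

#' Read a known-factor table
#'
#' Reads a delimited per-cell covariate table keyed by cell ID (first column)
#' and aligns it to the cells of a count matrix. Missing values are rejected.
#'
#' @param path TSV/CSV path with header; first column holds cell IDs.
#' @param cell_ids Optional character vector; rows are reordered to match and
#'   missing cells are an error.
#' @param sep Field separator; guessed from extension when `NULL`.
#' @return A data.frame, one row per cell.
#' @export
read_factors <- function(path, cell_ids = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (anyNA(tab)) stop("known-factor table contains missing values")
  if (!is.null(cell_ids)) {
    missing <- setdiff(cell_ids, rownames(tab))
    if (length(missing)) {
      stop("factor table lacks cells: ", paste(missing, collapse = ", "))
    }
    tab <- tab[cell_ids, , drop = FALSE]
  }
  tab
}

#' Build a numeric design matrix from known factors
#'
#' Encodes a per-cell covariate table as a numeric design matrix with a
#' leading intercept column: categorical covariates are one-hot encoded with
#' the first level as reference, numeric covariates pass through, and any
#' previously estimated surrogate variables are appended last. Covariates
#' that are constant after encoding are dropped with a warning; collinearity
#' is tolerated (downstream fitting uses a pseudoinverse).
#'
#' @param factors Data.frame/matrix/vector of per-cell covariates, or `NULL`
#'   for an intercept-only design.
#' @param n Number of cells; required when `factors` is `NULL`, otherwise
#'   checked against it.
#' @param svs Optional numeric matrix of surrogate-variable columns to append.
#' @return Numeric matrix with `n` rows; first column is the intercept.
#' @export
build_design <- function(factors = NULL, n = NULL, svs = NULL) {
  if (!is.null(factors)) {
    if (is.vector(factors) || is.factor(factors)) {
      factors <- data.frame(factor1 = factors)
    }
    factors <- as.data.frame(factors, stringsAsFactors = FALSE)
    if (anyNA(factors)) stop("known factors contain missing values")
    if (is.null(n)) n <- nrow(factors)
    if (nrow(factors) != n) stop("factor rows do not match cell count")
  }
  if (is.null(n)) stop("supply factors or n")
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(factors)) {
    for (nm in names(factors)) {
      v <- factors[[nm]]
      if (is.numeric(v)) {
        cols <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      } else {
        f <- factor(v)
        lev <- levels(f)
        if (length(lev) < 2) {
          warning("covariate '", nm, "' is constant; dropped")
          next
        }
        cols <- vapply(lev[-1], function(l) as.numeric(f == l), numeric(n))
        colnames(cols) <- paste0(nm, lev[-1])
      }
      keep <- apply(cols, 2, function(x) length(unique(x)) > 1)
      if (!all(keep)) warning("constant column(s) in covariate '", nm, "' dropped")
      cols <- cols[, keep, drop = FALSE]
      if (ncol(cols)) X <- cbind(X, cols)
    }
  }
  if (!is.null(svs)) {
    svs <- as.matrix(svs)
    if (nrow(svs) != n) stop("SV rows do not match cell count")
    if (is.null(colnames(svs))) colnames(svs) <- paste0("SV", seq_len(ncol(svs)))
    X <- cbind(X, svs)
  }
  X
}
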