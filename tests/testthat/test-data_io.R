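test_that("dense tables read back identically in both orientations", {
  m <- toy_counts()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(m, tsv, sep = "\t", quote = FALSE, col.names = NA)
  got <- read_counts(tsv, layout = "cells-by-genes")
  expect_equal(got, m)

  # same matrix stored genes-by-cells comes back transposed to cells x genes
  write.table(t(m), tsv, sep = "\t", quote = FALSE, col.names = NA)
  got2 <- read_counts(tsv, layout = "genes-by-cells")
  expect_equal(got2, m)
})

test_that("Matrix Market round-trip preserves values and IDs", {
  set.seed(42)
  m <- matrix(rpois(15 * 8, 2), 15, 8,
              dimnames = list(paste0("c", 1:15), paste0("g", 1:8)))
  storage.mode(m) <- "double"
  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_counts(m, mtx)
  got <- read_counts(mtx, layout = "cells-by-genes")
  expect_equal(got, m)
})

test_that("invalid counts are rejected", {
  bad <- toy_counts(); bad[1, 1] <- -1
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, tsv, sep = "\t", quote = FALSE, col.names = NA)
  expect_error(read_counts(tsv), "non-negative")
  bad2 <- toy_counts(); bad2[1, 1] <- 0.5
  write.table(bad2, tsv, sep = "\t", quote = FALSE, col.names = NA)
  expect_error(read_counts(tsv), "integral")
})

test_that("gene filter applies the strict >min_count in >=min_cells rule", {
  cols <- cbind(a = c(6, 6, 6, 0, 0),
                b = c(6, 6, 0, 0, 0),
                c = c(5, 5, 5, 5, 5))
  rownames(cols) <- paste0("c", 1:5)
  kept <- filter_genes(cols)
  expect_identical(colnames(kept), "a")
  # idempotent
  expect_equal(filter_genes(kept), kept)
  expect_warning(out <- filter_genes(cols[, "c", drop = FALSE]), "removed")
  expect_equal(ncol(out), 0L)
})

test_that("median-library normalization equalizes cell totals and preserves proportions", {
  set.seed(7)
  m <- matrix(rpois(3 * 6, 10) + 1, 3, 6,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:6)))
  norm <- normalize_median_library(m)
  med <- median(rowSums(m))
  expect_equal(unname(rowSums(norm)), rep(med, 3))
  # element-wise hand computation
  expect_equal(norm, m * (med / rowSums(m)), tolerance = 1e-12)
  # proportions unchanged
  expect_equal(norm / rowSums(norm)[row(norm)], m / rowSums(m)[row(m)],
               tolerance = 1e-12)
  # single cell: unchanged
  one <- m[1, , drop = FALSE]
  expect_equal(normalize_median_library(one), one)
  zero <- rbind(m, c0 = rep(0, 6))
  expect_error(normalize_median_library(zero), "c0")
})

test_that("log transform and geometric library size match elementwise formulas", {
  expect_equal(log_transform(matrix(c(0, 1, exp(1) - 1), 1)),
               matrix(c(0, log(2), 1), 1))
  expect_error(log_transform(matrix(-1)), "non-negative")

  set.seed(11)
  m <- matrix(rpois(4 * 5, 3), 4, 5)
  expect_equal(unname(geometric_library_size(m)),
               apply(m, 1, function(x) sum(log(1 + x))))
  expect_equal(geometric_library_size(m),
               geometric_library_size(m[, 5:1]))
  expect_equal(unname(geometric_library_size(matrix(0, 2, 3))), c(0, 0))
  expect_equal(unname(geometric_library_size(matrix(c(0, 1), 1))), log(2))
})

test_that("design matrices encode factors with intercept and reference level", {
  X <- build_design(data.frame(g = c("A", "A", "B")))
  expect_equal(unname(X), cbind(c(1, 1, 1), c(0, 0, 1)))

  X0 <- build_design(NULL, n = 4)
  expect_equal(unname(X0), matrix(1, 4, 1))

  sv <- matrix(rnorm(3), 3, 1)
  X2 <- build_design(data.frame(g = c("A", "B", "B"), age = c(1, 2, 3)),
                     svs = sv)
  expect_equal(ncol(X2), 4L)
  expect_identical(colnames(X2)[1], "(Intercept)")
  expect_equal(unname(X2[, 4]), as.vector(sv))

  expect_warning(Xc <- build_design(data.frame(g = c("A", "A", "A"))),
                 "constant")
  expect_equal(ncol(Xc), 1L)
  expect_error(build_design(data.frame(g = c("A", NA, "B"))), "missing")
})

test_that("factor tables are aligned to cell IDs and NAs rejected", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(id = c("c2", "c1"), sex = c("M", "F"), age = c(5, 7))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_factors(tsv, cell_ids = c("c1", "c2"))
  expect_identical(rownames(got), c("c1", "c2"))
  expect_identical(got$sex, c("F", "M"))
  expect_error(read_factors(tsv, cell_ids = c("c1", "c3")), "c3")
})
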