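write_mm <- function(path, nrow, ncol, entries) {
  # entries: matrix with columns i, j, x
  lines <- c("%%MatrixMarket matrix coordinate integer general",
    paste(nrow, ncol, nrow(entries)),
    apply(entries, 1, paste, collapse = " "))
  writeLines(lines, path)
}

test_that("TSV count matrices are read with genes as rows", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "counts.tsv")
  df <- data.frame(gene = c("g1", "g2", "g3"), c1 = 0L, c2 = 0L,
    c3 = 0L, c4 = 0L)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- read_count_matrix(tsv)
  expect_s3_class(cm, "count_matrix")
  expect_identical(dim(cm$counts), c(3L, 4L))
  expect_true(all(cm$counts == 0))
  expect_identical(cm$gene_ids, c("g1", "g2", "g3"))
})

test_that("Matrix Market entries expand and duplicates sum", {
  d <- withr::local_tempdir()
  mm <- file.path(d, "m.mtx")
  writeLines(c("ga", "gb"), file.path(d, "genes.txt"))
  writeLines(c("c1", "c2", "c3"), file.path(d, "cells.txt"))

  write_mm(mm, 2, 3, rbind(c(1, 1, 5), c(2, 3, 2)))
  cm <- read_count_matrix(mm, file.path(d, "genes.txt"),
    file.path(d, "cells.txt"))
  expect_equal(unname(cm$counts), rbind(c(5, 0, 0), c(0, 0, 2)))

  # duplicated coordinates sum (oracle: naive sum over the coordinate list)
  write_mm(mm, 2, 3, rbind(c(1, 1, 2), c(1, 1, 3)))
  cm <- read_count_matrix(mm, file.path(d, "genes.txt"),
    file.path(d, "cells.txt"))
  expect_equal(cm$counts[1, 1], 2 + 3)
})

test_that("Matrix Market orientation is resolved by sidecar lengths", {
  d <- withr::local_tempdir()
  mm <- file.path(d, "m.mtx")
  writeLines(c("ga", "gb"), file.path(d, "genes.txt"))
  writeLines(c("c1", "c2", "c3"), file.path(d, "cells.txt"))
  # stored as cells x genes: auto-detect must transpose
  write_mm(mm, 3, 2, rbind(c(1, 1, 7), c(3, 2, 4)))
  cm <- read_count_matrix(mm, file.path(d, "genes.txt"),
    file.path(d, "cells.txt"))
  expect_identical(dim(cm$counts), c(2L, 3L))
  expect_equal(cm$counts["ga", "c1"], 7)
  expect_equal(cm$counts["gb", "c3"], 4)
  # mismatched sidecars are an error
  writeLines(c("ga", "gb", "gc", "gd"), file.path(d, "genes.txt"))
  expect_error(read_count_matrix(mm, file.path(d, "genes.txt"),
    file.path(d, "cells.txt")), "sidecar")
})

test_that("invalid count entries are rejected", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "counts.tsv")
  writeLines(c("gene\tc1\tc2", "g1\t1\t-2", "g2\t0\t3"), tsv)
  expect_error(read_count_matrix(tsv), "negative")
  writeLines(c("gene\tc1\tc2", "g1\t1\t2.5", "g2\t0\t3"), tsv)
  expect_error(read_count_matrix(tsv), "non-integer")
  writeLines(c("gene\tc1\tc2", "g1\t1\t2", "g1\t0\t3"), tsv)
  expect_error(read_count_matrix(tsv))
})

make_cm <- function(counts, genes, cells) {
  dimnames(counts) <- list(genes, cells)
  structure(list(gene_ids = genes, cell_ids = cells, counts = counts),
    class = "count_matrix")
}

test_that("build_trajectory orders cells and computes size factors", {
  counts <- matrix(rpois(3 * 12, 5) + 1, 3, 12)
  cells <- sprintf("c%02d", 1:12)
  cm <- make_cm(counts, c("g1", "g2", "g3"), cells)
  pt <- data.frame(cell_id = cells, pseudotime = rev(seq_len(12)) / 12)
  td <- build_trajectory(cm, pt)
  expect_identical(td$cell_ids, rev(cells))
  expect_equal(td$M, unname(colSums(counts))[12:1])
  expect_equal(td$M_tilde, median(colSums(counts)))
  expect_equal(td$N, 12L)

  # even-length median is the midpoint mean
  counts4 <- matrix(c(100, 200, 300, 1000), 1, 4)
  cm4 <- make_cm(counts4, "g1", paste0("c", 1:4))
  pt4 <- data.frame(cell_id = paste0("c", 1:4), pseudotime = 1:4)
  expect_error(build_trajectory(cm4, pt4), "too few cells")
  counts10 <- cbind(counts4, matrix(rep(c(100, 200, 300), 2), 1, 6))
  cm10 <- make_cm(counts10, "g1", paste0("c", 1:10))
  pt10 <- data.frame(cell_id = paste0("c", 1:10), pseudotime = 1:10)
  expect_equal(build_trajectory(cm10, pt10)$M_tilde, 200)

  # unknown cells are an error; missing pseudotime drops with a message
  expect_error(build_trajectory(cm,
    data.frame(cell_id = c(cells, "nope"), pseudotime = 1:13)), "nope")
  expect_message(
    td2 <- build_trajectory(cm, pt[1:11, ]), "dropping 1")
  expect_equal(td2$N, 11L)
})

test_that("build_trajectory is invariant to input cell order and breaks ties", {
  set.seed(4)
  counts <- matrix(rpois(5 * 20, 3) + 1, 5, 20)
  cells <- sprintf("c%02d", 1:20)
  cm <- make_cm(counts, paste0("g", 1:5), cells)
  ptv <- round(runif(20), 1)  # forces ties
  pt <- data.frame(cell_id = cells, pseudotime = ptv)
  td1 <- build_trajectory(cm, pt)
  perm <- sample(20)
  cm2 <- make_cm(counts[, perm], paste0("g", 1:5), cells[perm])
  td2 <- build_trajectory(cm2, pt[perm, ])
  expect_identical(td1$cell_ids, td2$cell_ids)
  expect_identical(td1$counts, td2$counts)
  expect_identical(td1$M, td2$M)
})

test_that("zero-UMI cells are rejected at ingest", {
  counts <- matrix(1, 2, 12)
  counts[, 5] <- 0
  cm <- make_cm(counts, c("g1", "g2"), sprintf("c%02d", 1:12))
  pt <- data.frame(cell_id = sprintf("c%02d", 1:12), pseudotime = 1:12)
  expect_error(build_trajectory(cm, pt), "zero total UMIs")
})

test_that("gene filter is boundary-inclusive and idempotent", {
  N <- 100
  counts <- rbind(
    one_cell = c(1, rep(0, N - 1)),   # exactly 1% of cells
    zero = rep(0, N),
    dense = rpois(N, 2) + 1)
  cm <- make_cm(counts, rownames(counts), sprintf("c%03d", 1:N))
  pt <- data.frame(cell_id = sprintf("c%03d", 1:N), pseudotime = 1:N)
  td <- build_trajectory(cm, pt)
  f <- filter_genes(td, 0.01)
  expect_true("one_cell" %in% f$gene_ids)    # >= 1% is retained
  expect_false("zero" %in% f$gene_ids)
  expect_identical(filter_genes(td, 0)$gene_ids, td$gene_ids)
  f2 <- filter_genes(f, 0.01)
  expect_identical(f2$gene_ids, f$gene_ids)
  expect_identical(f2$counts, f$counts)
})

test_that("fit results round-trip through disk", {
  genes <- list(
    gene_spec("gs", "sigmoidal", c(k = 0.15, L = 2, t0 = 60, bmin = 0.3)),
    gene_spec("gu", "uniform", c(b = 1)))
  td <- sim_td(genes, N = 120, seed = 3)
  fits <- list(
    quick_fit(td, "gs", seed = 2, its = 500, burn = 250, nsub = 50),
    quick_fit(td, "gu", seed = 2, its = 500, burn = 250, nsub = 50))

  d <- withr::local_tempdir()
  paths <- write_fit_results(fits, d, metadata = list(seed = 2))
  summ <- read.delim(paths$summary)
  expect_equal(nrow(summ), 2L)
  expect_length(paths$samples, 2L)

  back <- read_fit_samples(paths$samples[[1]])
  draws <- fits[[1]]$posterior$draws
  expect_equal(nrow(back), nrow(draws))
  for (cn in colnames(draws)) {
    # 12+ significant digits survive the text round-trip
    expect_equal(back[[cn]], unname(draws[, cn]), tolerance = 1e-12)
  }
  meta <- jsonlite::read_json(paths$metadata)
  expect_equal(meta$seed, 2)

  # empty input still yields a header-only summary
  paths0 <- write_fit_results(list(), withr::local_tempdir())
  expect_equal(nrow(read.delim(paths0$summary)), 0L)
})
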