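mk_expr_fixture <- function(dir) {
  counts <- matrix(c(0, 5, 10, 0,
                     2, 0, 0, 8,
                     1, 1, 1, 1), nrow = 3, byrow = TRUE)
  genes <- c("G1", "G2", "G3")
  cells <- paste0("c", 1:4)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(genes, file.path(dir, "genes.txt"))
  writeLines(cells, file.path(dir, "cells.txt"))
  utils::write.table(
    data.frame(cell_id = cells,
               cell_type = c("astro", "astro", "neuron", "neuron"),
               condition = c("WT", "WT", "WT", "PD")),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  list(counts = counts, genes = genes, cells = cells)
}

test_that("the MTX triplet fixture loads with its annotations", {
  dir <- withr::local_tempdir()
  fx <- mk_expr_fixture(dir)
  em <- read_expression(file.path(dir, "counts.mtx"),
                        file.path(dir, "genes.txt"),
                        file.path(dir, "cells.txt"),
                        file.path(dir, "labels.tsv"))
  expect_equal(as.matrix(em$counts), fx$counts, ignore_attr = TRUE)
  expect_identical(em$gene_ids, fx$genes)
  expect_identical(em$cell_type, c("astro", "astro", "neuron", "neuron"))
})

test_that("label gaps and empty matrices are rejected", {
  dir <- withr::local_tempdir()
  mk_expr_fixture(dir)
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  utils::write.table(lab[-2, ], file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_expression(file.path(dir, "counts.mtx"),
                               file.path(dir, "genes.txt"),
                               file.path(dir, "cells.txt"),
                               file.path(dir, "labels.tsv")),
               "missing cell id: c2")
  expect_error(expression_matrix(matrix(0, 3, 0), c("a", "b", "c"),
                                 character(), character(), character()),
               "no cells")
  expect_error(expression_matrix(matrix(1, 2, 2), c("a", "b"), c("x", "y"),
                                 c("t", "t"), c("w", NA)),
               "exactly one")
})

test_that("cell types are retained per the shared-presence rule", {
  em <- expression_matrix(
    matrix(1, 1, 120), "G", sprintf("c%03d", 1:120),
    cell_type = c(rep("astro", 60), rep("oligo", 12), rep("neuron", 48)),
    condition = c(rep("WT", 30), rep("PD", 30), rep("WT", 12),
                  rep("WT", 24), rep("PD", 24)))
  # oligo has cells only in WT: excluded when both conditions are required
  ret <- filter_cell_types(em, min_cells = 10, require_shared = TRUE)
  expect_setequal(unique(ret$cell_type), c("astro", "neuron"))
  # the 12-cell cluster falls below a 50-cell threshold
  expect_warning(ret2 <- filter_cell_types(em, min_cells = 50,
                                           require_shared = FALSE),
                 "no cell type")
  expect_equal(nrow(ret2), 0)
  # without sharing, oligo survives in the condition where it has cells
  ret3 <- filter_cell_types(em, min_cells = 12, require_shared = FALSE)
  expect_true(all(ret3$n_cells >= 12))
  expect_true("oligo" %in% ret3$cell_type)
  # permissive call retains every observed type
  ret4 <- filter_cell_types(em, min_cells = 1, require_shared = FALSE)
  expect_setequal(unique(ret4$cell_type), c("astro", "oligo", "neuron"))
})

test_that("pseudobulk applies per-cell counts-per-10k log2 then averages", {
  # two cells with library size 10k and counts 10 and 30 for gene G1:
  # normalized counts stay 10 and 30, so the value is mean(log2(11), log2(31))
  counts <- rbind(G1 = c(10, 30), FILL = c(9990, 9970))
  em <- expression_matrix(counts, rownames(counts), c("c1", "c2"),
                          c("t", "t"), c("w", "w"))
  pb <- pseudobulk(em, "w", "t")
  expect_equal(unname(pb["G1"]), mean(c(log2(11), log2(31))))
  # single cell, zero count -> 0
  em1 <- expression_matrix(matrix(c(0, 5), 2), c("G1", "G2"), "c1", "t", "w")
  expect_equal(unname(pseudobulk(em1, "w", "t")["G1"]), 0)
  expect_error(pseudobulk(em1, "w", "missing"), "empty stratum")
})

test_that("pseudobulk is invariant to uniform count scaling", {
  set.seed(5)
  counts <- matrix(rpois(60, 5), nrow = 6)
  em1 <- expression_matrix(counts, paste0("g", 1:6), paste0("c", 1:10),
                           rep("t", 10), rep("w", 10))
  em2 <- expression_matrix(2 * counts, paste0("g", 1:6), paste0("c", 1:10),
                           rep("t", 10), rep("w", 10))
  expect_equal(pseudobulk(em1, "w", "t"), pseudobulk(em2, "w", "t"))
})

test_that("discretization recovers the expressed component of a mixture", {
  # oracle: simulate a labelled two-mode mixture; genes drawn from the upper
  # mode must come back as core near-completely once modes are 4+ sd apart
  set.seed(101)
  for (rep in 1:5) {
    n_lo <- 150; n_hi <- 120
    lo <- pmax(stats::rnorm(n_lo, 1, 0.6), 0.05)
    hi <- stats::rnorm(n_hi, 6, 1)
    expr <- stats::setNames(c(lo, hi),
                            c(paste0("lo", 1:n_lo), paste0("hi", 1:n_hi)))
    d <- discretize(expr)
    recovery <- mean(paste0("hi", 1:n_hi) %in% d$core)
    purity <- mean(!paste0("lo", 1:n_lo) %in% d$core)
    expect_gte(recovery, 0.99)
    expect_gte(purity, 0.95)
  }
})

test_that("discretization edge rules hold", {
  expr <- c(zero = 0, low = 0.5, mid = 3, high = 7)
  d <- discretize(expr)
  expect_false("zero" %in% d$core)   # all-zero gene is never core
  # forcing the threshold just below one gene adds exactly that gene
  d1 <- discretize(expr, params = list(upper = 6.9, lower = 1))
  d2 <- discretize(expr, params = list(upper = 2.9, lower = 1))
  expect_identical(d1$core, "high")
  expect_setequal(d2$core, c("mid", "high"))
  # lower upper threshold gives a superset (monotone)
  expect_true(all(d1$core %in% d2$core))
  # degenerate distribution warns and falls back to percentiles
  expect_warning(discretize(stats::setNames(rep(2, 20), paste0("g", 1:20))),
                 "degenerate")
})

test_that("discretization ignores gene and cell order", {
  set.seed(7)
  expr <- stats::setNames(c(stats::rnorm(100, 1, 0.5),
                            stats::rnorm(80, 6, 0.8)), paste0("g", 1:180))
  d1 <- discretize(expr)
  perm <- sample(length(expr))
  d2 <- discretize(expr[perm])
  expect_setequal(d1$core, d2$core)
  expect_equal(d1$upper, d2$upper)
})
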