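make_planted_matrix <- function(bi, bj, count, n_bins = 100, bs = 2000) {
  interaction_matrix("1", bs, bins_i = bi, bins_j = bj, counts = count,
                     n_bins = n_bins)
}

test_that("filter_genes applies the uniqueness, chromosome and length rules", {
  ann <- data.frame(
    name = c("A", "B", "B", "C", "D", "E"),
    chrom = c("1", "2", "7", "chrY", "X", "3"),
    strand = c("+", "+", "+", "+", "-", "+"),
    txStart = c(1000, 2000, 2000, 3000, 10000, 4000),
    txEnd = c(9000, 8000, 8000, 9000, 18000, 4800))
  g <- filter_genes(ann, bin_size = 2000)
  # duplicated symbol B removed everywhere; chrY dropped; E shorter than bin
  expect_setequal(g$symbol, c("A", "D"))
  # minus strand: TSS is the larger coordinate
  expect_equal(g$tss[g$symbol == "D"], 18000)
  expect_equal(g$tes[g$symbol == "D"], 10000)
  expect_true(any(grepl("duplicate:B", attr(g, "skipped"))))
  expect_true(any(grepl("short:E", attr(g, "skipped"))))
})

test_that("tss_tes_count reads the right bin pair, symmetrically", {
  m <- make_planted_matrix(c(2, 5), c(9, 5), c(7, 3))
  gene <- list(symbol = "G", chrom = "1", tss = 4100, tes = 19900,
               length = 15800)
  expect_equal(tss_tes_count(m, gene), 7)
  # swapping TSS and TES yields the identical raw count
  swapped <- list(symbol = "G", chrom = "1", tss = 19900, tes = 4100,
                  length = 15800)
  expect_equal(tss_tes_count(m, swapped), 7)
  # TSS and TES in the same bin reads the diagonal
  diag_gene <- list(symbol = "H", chrom = "1", tss = 10100, tes = 11900,
                    length = 1800)
  expect_equal(tss_tes_count(m, diag_gene), 3)
  # empty matrix -> 0
  m0 <- make_planted_matrix(integer(0), integer(0), numeric(0))
  expect_equal(tss_tes_count(m0, gene), 0)
  wrong <- list(symbol = "W", chrom = "2", tss = 1, tes = 5000, length = 4999)
  expect_error(tss_tes_count(m, wrong), "chromosome")
  outside <- list(symbol = "O", chrom = "1", tss = 1, tes = 5e6, length = 5e6)
  expect_error(tss_tes_count(m, outside), "extent")
})

test_that("length_normalize is calibrated, scale-invariant and flagged", {
  nb <- 150
  idx <- which(upper.tri(matrix(0, nb, nb), diag = TRUE), arr.ind = TRUE)
  m <- interaction_matrix("1", 2000, idx[, 1] - 1L, idx[, 2] - 1L,
                          rep(4, nrow(idx)), n_bins = nb)
  gene <- list(symbol = "G", chrom = "1", tss = 10000, tes = 110000,
               length = 1e5)
  cnt <- tss_tes_count(m, gene)
  r <- length_normalize(m, gene, cnt, n_samples = 3000, seed = 1)
  expect_equal(as.double(r), 1, tolerance = 0.02)
  # doubling every entry leaves the ratio unchanged
  m2 <- interaction_matrix("1", 2000, idx[, 1] - 1L, idx[, 2] - 1L,
                           rep(8, nrow(idx)), n_bins = nb)
  r2 <- length_normalize(m2, gene, tss_tes_count(m2, gene),
                         n_samples = 3000, seed = 1)
  expect_equal(as.double(r), as.double(r2), tolerance = 1e-12)
  # empty matrix: zero baseline -> ratio 0, flagged
  m0 <- make_planted_matrix(integer(0), integer(0), numeric(0), n_bins = nb)
  r0 <- length_normalize(m0, gene, 0, n_samples = 100, seed = 1)
  expect_equal(as.double(r0), 0)
  expect_true(isTRUE(attr(r0, "flagged")))
})

test_that("interaction_score matches the log-form oracle and is monotone", {
  # asinh(s) = log(s + sqrt(1 + s^2))
  oracle <- function(x) { s <- sqrt(x + 0.5); log(s + sqrt(1 + s^2)) }
  expect_equal(interaction_score(0), oracle(0), tolerance = 1e-12)
  expect_equal(interaction_score(0), 0.6585, tolerance = 1e-4)
  expect_equal(interaction_score(0.5), log(1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(interaction_score(0.5), 0.8814, tolerance = 1e-4)
  xs <- seq(0, 20, by = 0.25)
  expect_true(all(diff(interaction_score(xs)) > 0))
  expect_error(interaction_score(-0.1), ">= 0")
})

test_that("score_genes ranks planted looped genes above background", {
  spec <- synth_spec(seed = 21, n_genes = 120)
  ia <- synth_interaction_data(spec)
  genes <- filter_genes(ia$annotation, bin_size = spec$bin_size)
  expect_false(any(c("SYNDUP", "SYNSHORT1", "SYNSHORT2") %in% genes$symbol))
  sc <- score_genes(ia$matrix, genes, n_samples = 1500, seed = 2)
  j <- merge(sc, ia$truth, by = "symbol")
  p <- wilcox.test(j$score[j$looped], j$score[!j$looped],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})
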