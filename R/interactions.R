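#' @title TSS-TES chromatin-interaction scoring
#' @name genomewide_interactions
#' @description
#' Per-gene 3'-5' interaction scores from binned (HiC-style) chromatin
#' contact matrices: the raw contact count between the bins holding a gene's
#' transcription start and end sites, length-normalised against random
#' intervals of the same length on the same chromosome, then passed through
#' the variance-stabilising `arcsinh sqrt(x + 0.5)` transform.
#' Coordinates are 0-based half-open (BED convention); the bin index of a
#' position is `floor(pos / bin_size)`.
NULL

#' Construct a binned interaction matrix
#'
#' @param chrom chromosome label
#' @param bin_size bin size in bp (> 0; 2000 by default, 1000 and 7000 are
#'   common alternatives)
#' @param bins_i,bins_j 0-based bin indices of the triplet entries
#' @param counts non-negative counts (symmetrised: `count(i,j) = count(j,i)`)
#' @param n_bins number of bins covered by the matrix (chromosome extent /
#'   bin size); inferred from the largest index if missing
#' @return an object of class `interaction_matrix` wrapping a sparse
#'   symmetric [Matrix::sparseMatrix()]
#' @export
interaction_matrix <- function(chrom, bin_size = 2000L, bins_i = integer(0),
                               bins_j = integer(0), counts = numeric(0),
                               n_bins = NULL) {
  .check(bin_size > 0, "bin_size must be > 0")
  .check(length(bins_i) == length(bins_j) &&
           length(bins_i) == length(counts), "triplet lengths differ")
  .check(all(counts >= 0), "counts must be >= 0")
  .check(all(bins_i >= 0) && all(bins_j >= 0), "bin indices are 0-based")
  if (is.null(n_bins))
    n_bins <- max(c(bins_i, bins_j, 0L)) + 1L
  # store the upper triangle once; symmetry is implied
  i <- pmin(bins_i, bins_j); j <- pmax(bins_i, bins_j)
  m <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = counts,
                            dims = c(n_bins, n_bins), symmetric = TRUE)
  structure(list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
                 m = m, n_bins = as.integer(n_bins)),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix %s: %d bins of %d bp, %d non-zero pairs\n",
              x$chrom, x$n_bins, x$bin_size,
              length(x$m@x)))
  invisible(x)
}

#' Filter a gene annotation to scoreable gene models
#'
#' Keeps genes with unique symbols on chromosomes 1-22 and X, drops genes
#' shorter than the matrix resolution, and assigns TSS/TES by strand (TSS is
#' `txStart` on `+`, `txEnd` on `-`).  Malformed records are skipped with a
#' log attribute.
#'
#' @param annotation data frame with columns `name` (symbol), `chrom`,
#'   `strand`, `txStart`, `txEnd` (refGene-style; `chrom` may carry a
#'   `chr` prefix)
#' @param bin_size matrix resolution in bp
#' @return data frame of gene models (`symbol`, `chrom`, `strand`, `tss`,
#'   `tes`, `length`) with attribute `skipped` listing dropped records
#' @export
filter_genes <- function(annotation, bin_size = 2000L) {
  a <- as.data.frame(annotation)
  need <- c("name", "chrom", "strand", "txStart", "txEnd")
  .check(all(need %in% names(a)), "annotation needs columns %s",
         paste(need, collapse = ", "))
  skipped <- character(0)
  chrom <- sub("^chr", "", as.character(a$chrom))
  ok_chrom <- chrom %in% c(as.character(1:22), "X")
  ok_strand <- a$strand %in% c("+", "-")
  ok_coord <- is.finite(a$txStart) & is.finite(a$txEnd) &
    a$txEnd > a$txStart
  malformed <- !(ok_strand & ok_coord)
  if (any(malformed))
    skipped <- c(skipped, paste0("malformed:", a$name[malformed]))
  a <- a[ok_chrom & !malformed, , drop = FALSE]
  chrom <- chrom[ok_chrom & !malformed]
  dup <- a$name %in% a$name[duplicated(a$name)]
  if (any(dup)) skipped <- c(skipped, paste0("duplicate:", unique(a$name[dup])))
  a <- a[!dup, , drop = FALSE]; chrom <- chrom[!dup]
  len <- a$txEnd - a$txStart
  short <- len < bin_size
  if (any(short)) skipped <- c(skipped, paste0("short:", a$name[short]))
  a <- a[!short, , drop = FALSE]; chrom <- chrom[!short]; len <- len[!short]
  out <- data.frame(symbol = a$name, chrom = chrom, strand = a$strand,
                    tss = ifelse(a$strand == "+", a$txStart, a$txEnd),
                    tes = ifelse(a$strand == "+", a$txEnd, a$txStart),
                    length = len, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

# vectorised symmetric lookup of (i, j) 0-based bin pairs
.matrix_counts <- function(mat, bi, bj) {
  i <- pmin(bi, bj) + 1L; j <- pmax(bi, bj) + 1L
  as.double(mat$m[cbind(i, j)])
}

#' Raw TSS-TES contact count of a gene
#'
#' @param mat an [interaction_matrix()]
#' @param gene one row of a [filter_genes()] result (list-like with `chrom`,
#'   `tss`, `tes`)
#' @return the matrix count between the bin containing the TSS and the bin
#'   containing the TES
#' @export
tss_tes_count <- function(mat, gene) {
  .check(inherits(mat, "interaction_matrix"), "mat must be interaction_matrix")
  .check(identical(as.character(gene$chrom), mat$chrom),
         "gene %s is on chromosome %s, matrix covers %s",
         gene$symbol %||% "?", gene$chrom, mat$chrom)
  bi <- floor(gene$tss / mat$bin_size)
  bj <- floor(gene$tes / mat$bin_size)
  .check(bi >= 0 && bj >= 0 && bi < mat$n_bins && bj < mat$n_bins,
         "gene coordinates fall outside the matrix extent")
  .matrix_counts(mat, bi, bj)
}

#' Length-normalised interaction ratio
#'
#' Divides a gene's TSS-TES count by the mean count over `n_samples` random
#' intervals of the same length placed uniformly (with replacement) within
#' the chromosome extent covered by the matrix, scoring the same
#' (start-bin, end-bin) geometry as the gene.
#'
#' @param mat an [interaction_matrix()]
#' @param gene gene model row (needs `length`)
#' @param count the raw TSS-TES count (from [tss_tes_count()])
#' @param n_samples number of random intervals (default 1e4)
#' @param seed integer seed
#' @return the ratio (>= 0); if the baseline mean is zero the ratio is 0
#'   with attribute `flagged = TRUE`
#' @export
length_normalize <- function(mat, gene, count, n_samples = 1e4, seed = 1L) {
  .check(inherits(mat, "interaction_matrix"), "mat must be interaction_matrix")
  L <- gene$length
  extent <- mat$n_bins * mat$bin_size
  .check(L < extent, "chromosome extent too small to place intervals")
  set.seed(seed)
  start <- runif(n_samples, 0, extent - L)
  bi <- floor(start / mat$bin_size)
  bj <- floor((start + L) / mat$bin_size)
  base <- mean(.matrix_counts(mat, as.integer(bi), as.integer(bj)))
  if (base <= 0) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  count / base
}

#' Variance-stabilised interaction score
#'
#' `arcsinh(sqrt(x + 0.5))`, monotone increasing in the normalised ratio.
#'
#' @param x normalised ratio (>= 0)
#' @return the score (>= `asinh(sqrt(0.5))`)
#' @export
interaction_score <- function(x) {
  .check(all(is.finite(x)) && all(x >= 0), "x must be finite and >= 0")
  asinh(sqrt(x + 0.5))
}

#' Score all genes of one chromosome against its interaction matrix
#'
#' @param mat an [interaction_matrix()]
#' @param genes a [filter_genes()] result (rows on other chromosomes are
#'   ignored)
#' @param n_samples random intervals per gene for the length normalisation
#' @param seed master seed (per-gene sub-seeds are derived from it)
#' @return data frame `(symbol, raw_count, ratio, score, flagged)`
#' @export
score_genes <- function(mat, genes, n_samples = 1e4, seed = 1L) {
  g <- genes[as.character(genes$chrom) == mat$chrom, , drop = FALSE]
  rows <- lapply(seq_len(nrow(g)), function(i) {
    gene <- g[i, ]
    cnt <- tss_tes_count(mat, gene)
    ratio <- length_normalize(mat, gene, cnt, n_samples,
                              seed = sub_seed(seed, i))
    data.frame(symbol = gene$symbol, raw_count = cnt,
               ratio = as.double(ratio),
               score = interaction_score(as.double(ratio)),
               flagged = isTRUE(attr(ratio, "flagged")),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(symbol = character(0), raw_count = numeric(0),
                      ratio = numeric(0), score = numeric(0),
                      flagged = logical(0)))
  do.call(rbind, rows)
}
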