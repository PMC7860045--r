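#' @title Single-cell UMI noise estimation
#' @name scrnaseq_noise
#' @description
#' Per-gene negative-binomial fitting of raw UMI counts (no library-size
#' normalisation), the influenza-infection cell split, and per-condition
#' mean/noise comparison.  Counts are fitted directly (`kappa = 1`, no
#' background), reusing the flow-FISH inference machinery.
NULL

#' Construct a gene-by-cell UMI count matrix
#'
#' @param counts integer matrix (genes x cells), dense or
#'   [Matrix::sparseMatrix()]
#' @param genes gene symbols (unique, length `nrow`)
#' @param barcodes cell barcodes (unique, length `ncol`)
#' @param flu_genes optional character vector of influenza gene symbols
#' @return an object of class `umi_matrix`
#' @export
umi_matrix <- function(counts, genes = rownames(counts),
                       barcodes = colnames(counts), flu_genes = character(0)) {
  .check(!is.null(genes), "gene symbols required (rownames or genes=)")
  if (is.null(barcodes)) barcodes <- sprintf("CELL%05d", seq_len(ncol(counts)))
  .check(!anyDuplicated(genes) && !anyDuplicated(barcodes),
         "gene symbols and barcodes must be unique")
  .check(length(genes) == nrow(counts) && length(barcodes) == ncol(counts),
         "dimension mismatch")
  .check(min(counts) >= 0, "counts must be non-negative")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  dimnames(counts) <- list(genes, barcodes)
  structure(list(counts = counts, flu_genes = as.character(flu_genes)),
            class = "umi_matrix")
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("umi_matrix: %d genes x %d cells (%d flu genes)\n",
              nrow(x$counts), ncol(x$counts), length(x$flu_genes)))
  invisible(x)
}

#' Filter to expressed genes
#'
#' Retains genes whose mean UMI count across cells strictly exceeds the
#' threshold (default 0.05).
#'
#' @param m a [umi_matrix()]
#' @param threshold expression threshold on the sample UMI mean
#' @return character vector of retained gene symbols
#' @export
filter_expressed <- function(m, threshold = 0.05) {
  .check(inherits(m, "umi_matrix"), "m must be a umi_matrix")
  mu <- Matrix::rowMeans(m$counts)
  names(mu)[mu > threshold]
}

#' Bayesian negative-binomial fit of one gene's UMI counts
#'
#' Counts are observed directly (identity measurement); medians and 90% HPD
#' intervals of `mu_X` and `k_on` are returned together with the derived
#' burst size `mu_X / k_on` and `CV2_X`.
#'
#' @param counts integer vector of per-cell UMI counts for one gene
#' @param priors a [default_priors()] object
#' @param seed integer seed
#' @param n_iter MCMC iterations
#' @return a one-row data frame (`mu_X`, `k_on`, `burst_size`, `CV2_X`, plus
#'   `*_lo`/`*_hi` HPD bounds); degenerate all-equal counts are flagged via
#'   the `flagged` column
#' @export
fit_gene_negbin <- function(counts, priors = default_priors("negative_binomial"),
                            seed = 1L, n_iter = 2000L) {
  flagged <- length(unique(counts)) == 1L
  ch <- adaptive_mh(as.double(counts), kind = "negative_binomial",
                    priors = priors, n_iter = n_iter, seed = seed,
                    background = NULL, pointwise_draws = 0L)
  s <- posterior_summary(ch)
  pick <- function(nm, col) s[s$parameter == nm, col]
  data.frame(mu_X = pick("mu_X", "median"),
             mu_X_lo = pick("mu_X", "hpd_lo"), mu_X_hi = pick("mu_X", "hpd_hi"),
             k_on = pick("k_on", "median"),
             k_on_lo = pick("k_on", "hpd_lo"), k_on_hi = pick("k_on", "hpd_hi"),
             burst_size = pick("burst_size", "median"),
             CV2_X = pick("CV2_X", "median"),
             flagged = flagged)
}

#' Method-of-moments negative-binomial estimates per gene
#'
#' Fast estimates used at genome scale and to initialise the MCMC:
#' `mu = mean`, `k_on = 1 / (CV2 - 1/mu)` (infinite when the sample is
#' under-dispersed relative to Poisson).
#'
#' @param m a [umi_matrix()]
#' @param symbols genes to estimate (default: expressed genes)
#' @return data frame `(symbol, mu_X, CV2_X, k_on, burst_size)`
#' @export
moments_negbin <- function(m, symbols = filter_expressed(m)) {
  .check(inherits(m, "umi_matrix"), "m must be a umi_matrix")
  x <- m$counts[symbols, , drop = FALSE]
  mu <- Matrix::rowMeans(x)
  v <- Matrix::rowMeans(x^2) - mu^2
  v <- v * ncol(x) / (ncol(x) - 1)
  cv2 <- v / mu^2
  excess <- cv2 - 1 / mu
  k_on <- ifelse(excess > 0, 1 / excess, Inf)
  data.frame(symbol = symbols, mu_X = as.double(mu), CV2_X = as.double(cv2),
             k_on = as.double(k_on),
             burst_size = as.double(mu / k_on), stringsAsFactors = FALSE)
}

#' Split cells into infected and uninfected by influenza UMI fraction
#'
#' A cell is infected iff at least 0.02% of its transcripts come from
#' influenza genes (inclusive threshold); a cell with zero total UMIs has
#' fraction 0.
#'
#' @param m a [umi_matrix()] with a non-empty `flu_genes` set (or pass
#'   `flu_genes`)
#' @param flu_genes influenza gene symbols (default `m$flu_genes`)
#' @param threshold infected fraction threshold (default 2e-4)
#' @return factor per cell with levels `uninfected`, `infected`
#' @export
infection_split <- function(m, flu_genes = m$flu_genes, threshold = 2e-4) {
  .check(inherits(m, "umi_matrix"), "m must be a umi_matrix")
  .check(length(flu_genes) > 0, "flu gene set must be non-empty")
  flu <- intersect(flu_genes, rownames(m$counts))
  tot <- Matrix::colSums(m$counts)
  fluc <- if (length(flu)) Matrix::colSums(m$counts[flu, , drop = FALSE])
    else rep(0, ncol(m$counts))
  frac <- ifelse(tot > 0, fluc / tot, 0)
  factor(ifelse(frac >= threshold, "infected", "uninfected"),
         levels = c("uninfected", "infected"))
}

#' Per-gene mean and noise comparison between conditions
#'
#' For each gene expressed in both conditions, computes the per-condition
#' mean and the distance `nu` from that condition's reference curve (with
#' its own sample-average burst frequency), then classifies genes into the
#' four quadrants of the (delta mu, delta nu) plane.
#'
#' @param m a [umi_matrix()]
#' @param labels factor from [infection_split()] (levels `uninfected`,
#'   `infected`)
#' @param expression_threshold per-condition expression filter
#' @return list with `table` (per-gene `mu_uninf`, `mu_inf`, `nu_uninf`,
#'   `nu_inf`, `quadrant`), `k_on_bar` per condition, `quadrant_fractions`,
#'   and `excluded` (genes expressed in only one condition)
#' @export
condition_noise_table <- function(m, labels, expression_threshold = 0.05) {
  .check(inherits(m, "umi_matrix"), "m must be a umi_matrix")
  labels <- factor(labels, levels = c("uninfected", "infected"))
  .check(all(table(labels) > 0), "both conditions must be non-empty")
  human <- setdiff(rownames(m$counts), m$flu_genes)
  est <- lapply(levels(labels), function(lv) {
    sub <- umi_matrix(m$counts[human, labels == lv, drop = FALSE])
    keep <- filter_expressed(sub, expression_threshold)
    e <- moments_negbin(sub, keep)
    e[is.finite(e$CV2_X) & e$CV2_X > 0, ]
  })
  names(est) <- levels(labels)
  k_on_bar <- vapply(est, function(e) {
    k <- e$k_on[is.finite(e$k_on) & e$k_on > 0]
    .check(length(k) > 0, "no overdispersed genes to average k_on over")
    mean(k)
  }, 0)
  common <- intersect(est$uninfected$symbol, est$infected$symbol)
  excluded <- setdiff(union(est$uninfected$symbol, est$infected$symbol),
                      common)
  u <- est$uninfected[match(common, est$uninfected$symbol), ]
  i <- est$infected[match(common, est$infected$symbol), ]
  nu_u <- nu_distance(u$mu_X, u$CV2_X, k_on_bar["uninfected"])
  nu_i <- nu_distance(i$mu_X, i$CV2_X, k_on_bar["infected"])
  dmu <- i$mu_X - u$mu_X; dnu <- nu_i - nu_u
  quad <- factor(ifelse(dmu < 0,
                        ifelse(dnu > 0, "upper_left", "lower_left"),
                        ifelse(dnu > 0, "upper_right", "lower_right")),
                 levels = c("upper_left", "upper_right", "lower_left",
                            "lower_right"))
  tab <- data.frame(symbol = common, mu_uninf = u$mu_X, mu_inf = i$mu_X,
                    nu_uninf = nu_u, nu_inf = nu_i, delta_mu = dmu,
                    delta_nu = dnu, quadrant = quad,
                    stringsAsFactors = FALSE)
  list(table = tab, k_on_bar = k_on_bar,
       quadrant_fractions = prop.table(table(quad)),
       excluded = excluded)
}
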