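#' Partition cells into cell-cycle phases and size groups
#'
#' Gates G1/S/G2 from the DNA-content histogram (valleys between the 2N and
#' 4N modes, detected on a kernel density estimate) and then splits each
#' phase into three size groups at the 0.33 and 0.99 quantiles of the FSC-A
#' signal.  A cell exactly at a breakpoint goes to the lower group.  The
#' valley heuristic is deliberately simple and configurable via `adjust`.
#'
#' @param data a [flowfish_dataset()] with `dna_content` and `fsc_a` channels
#' @param size_breaks FSC-A quantile breakpoints within each phase
#' @param adjust bandwidth adjustment passed to [stats::density()]
#' @return a data frame with columns `phase` (`G1`/`S`/`G2`), `size`
#'   (`small`/`medium`/`large`) and `group` (their interaction, up to 9
#'   levels); one row per cell.  If the S valley cannot be resolved the S
#'   phase is empty and the result carries attribute `flagged = TRUE`.
#' @export
partition_by_cycle_size <- function(data, size_breaks = c(0.33, 0.99),
                                    adjust = 1) {
  .check(inherits(data, "flowfish_dataset"), "data must be a flowfish_dataset")
  .check(!is.null(data$dna_content) && !is.null(data$fsc_a),
         "dna_content and fsc_a channels are required")
  dna <- data$dna_content; fsc <- data$fsc_a
  de <- density(dna, n = 512, adjust = adjust)
  ys <- de$y
  peaks <- which(diff(sign(diff(ys))) == -2) + 1L
  peaks <- peaks[ys[peaks] >= 0.05 * max(ys)]   # ignore density wiggles
  .check(length(peaks) >= 2,
         "DNA-content histogram is unimodal; cannot gate cell-cycle phases")
  # two tallest modes = 2N and 4N
  ord <- peaks[order(ys[peaks], decreasing = TRUE)]
  p2 <- sort(ord[1:2])
  between <- seq.int(p2[1], p2[2])
  valleys <- between[which(diff(sign(diff(ys[between]))) == 2) + 1L]
  .check(length(valleys) >= 1, "no valley between the DNA-content modes")
  # modes must be genuinely separated, not shoulders of one mode
  .check(min(ys[valleys]) < 0.75 * min(ys[p2]),
         "DNA-content histogram is effectively unimodal; cannot gate phases")
  flagged <- FALSE
  if (length(valleys) >= 2) {
    t1 <- de$x[valleys[1]]; t2 <- de$x[valleys[length(valleys)]]
  } else {
    t1 <- t2 <- de$x[valleys[1]]
    flagged <- TRUE               # no resolvable S population
  }
  phase <- ifelse(dna <= t1, "G1", ifelse(dna <= t2, "S", "G2"))
  size <- character(length(fsc))
  for (ph in unique(phase)) {
    idx <- phase == ph
    qs <- quantile(fsc[idx], probs = size_breaks, type = 7, names = FALSE)
    size[idx] <- ifelse(fsc[idx] <= qs[1], "small",
                        ifelse(fsc[idx] <= qs[2], "medium", "large"))
  }
  out <- data.frame(phase = factor(phase, levels = c("G1", "S", "G2")),
                    size = factor(size, levels = c("small", "medium",
                                                   "large")))
  out$group <- interaction(out$phase, out$size, drop = FALSE)
  if (flagged || length(unique(phase)) < 3) {
    attr(out, "flagged") <- TRUE
    warning("fewer than 3 cell-cycle phases resolved; groups flagged")
  }
  attr(out, "thresholds") <- c(t1 = t1, t2 = t2)
  out
}

#' Extrinsic/intrinsic decomposition of expression variability
#'
#' Law-of-total-variance split over cell groups: the extrinsic component is
#' the weighted variance of the group means, the intrinsic component the
#' weighted mean of the within-group variances; the two fractions sum to 1
#' exactly.  Standard errors are obtained by bootstrap over cells.
#'
#' Either supply per-cell `values` with a `groups` label vector, or a
#' summary data frame via `summary_stats` with columns `mean`, `var`,
#' `weight` (no bootstrap in that case).
#'
#' @param values numeric per-cell expression values
#' @param groups group label per cell (>= 2 distinct, no empty group)
#' @param n_boot bootstrap resamples for the SEs (default 1000)
#' @param seed seed for the bootstrap
#' @param summary_stats optional data frame of per-group `mean`, `var`,
#'   `weight`
#' @return list with `extrinsic`, `intrinsic` (fractions in `[0,1]` summing
#'   to 1), the absolute components `var_extrinsic`, `var_intrinsic`,
#'   `var_total`, and bootstrap `se_extrinsic`/`se_intrinsic` when cell-level
#'   data were given
#' @export
decompose_noise <- function(values = NULL, groups = NULL, n_boot = 1000L,
                            seed = 1L, summary_stats = NULL) {
  split_fracs <- function(mu, v, w) {
    w <- w / sum(w)
    m <- sum(w * mu)
    ext <- sum(w * (mu - m)^2)
    intr <- sum(w * v)
    tot <- ext + intr
    if (tot <= 0) return(c(ext = 0, int = 1, vext = 0, vint = 0, vtot = 0))
    c(ext = ext / tot, int = intr / tot, vext = ext, vint = intr, vtot = tot)
  }
  if (!is.null(summary_stats)) {
    s <- as.data.frame(summary_stats)
    .check(all(c("mean", "var", "weight") %in% names(s)),
           "summary_stats needs columns mean, var, weight")
    .check(nrow(s) >= 2, "need at least 2 groups")
    f <- split_fracs(s$mean, s$var, s$weight)
    return(list(extrinsic = unname(f["ext"]), intrinsic = unname(f["int"]),
                var_extrinsic = unname(f["vext"]),
                var_intrinsic = unname(f["vint"]),
                var_total = unname(f["vtot"]),
                se_extrinsic = NA_real_, se_intrinsic = NA_real_))
  }
  .check(!is.null(values) && !is.null(groups), "values and groups required")
  g <- as.factor(as.character(groups))
  .check(nlevels(g) >= 2, "need at least 2 groups")
  tab <- table(g)
  .check(all(tab > 0), "empty group: %s",
         paste(names(tab)[tab == 0], collapse = ","))
  stat <- function(v, gg) {
    mu <- tapply(v, gg, mean)
    # population (divide-by-n) within-group variance keeps the identity exact
    vv <- tapply(v, gg, function(z) mean((z - mean(z))^2))
    w <- tapply(v, gg, length)
    split_fracs(mu, vv, w)
  }
  f <- stat(values, g)
  set.seed(seed)
  n <- length(values)
  bs <- replicate(n_boot, {
    i <- sample.int(n, n, replace = TRUE)
    gi <- droplevels(g[i])
    if (nlevels(gi) < 2) c(NA, NA) else stat(values[i], gi)[1:2]
  })
  list(extrinsic = unname(f["ext"]), intrinsic = unname(f["int"]),
       var_extrinsic = unname(f["vext"]), var_intrinsic = unname(f["vint"]),
       var_total = unname(f["vtot"]),
       se_extrinsic = sd(bs[1, ], na.rm = TRUE),
       se_intrinsic = sd(bs[2, ], na.rm = TRUE))
}
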