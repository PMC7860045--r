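#' @title Synthetic data with known ground truth
#' @name synthetic_data
#' @description
#' Generators for every input the analysis consumes: flow-FISH fluorescence
#' with skew-normal background and optional DNA/FSC-A channels, control-line
#' background samples, calibration pairs, binned chromatin-interaction
#' matrices with planted looped genes, and UMI count matrices with an
#' influenza-infection structure.  Every generator is deterministic given
#' the master seed, and the returned truth records are sufficient to score
#' every downstream estimate.
NULL

#' Specification of a synthetic experiment
#'
#' Defaults emulate the regimes the inference targets: bursting rates in the
#' territory of inducible transgenes (dimensionless `k_off` well above
#' `k_on`), a skew-normal background well separated from zero, and a
#' measured scale of a few a.u. per molecule.
#'
#' @param seed master seed (every output derives its randomness from it)
#' @param kinetics a [kinetic_params()] object (per condition)
#' @param kind stationary model the counts are drawn from
#' @param measurement a [measurement_params()] object (per replicate)
#' @param n_cells cells per replicate
#' @param n_replicates number of replicates
#' @param condition condition label
#' @param phase_weights cell-cycle mixture weights (G1, S, G2)
#' @param phase_multipliers phase-specific multipliers on the mean
#'   expression (extrinsic component; all 1 keeps X strictly stationary)
#' @param calib_counts molecule-count grid of the calibration pairs
#' @param calib_cv coefficient of variation of the gamma calibration noise
#' @param n_genes gene-catalogue size of the interaction arm
#' @param looped_fraction fraction of genes with a planted 3'-5' loop
#' @param enrichment multiplicative TSS-TES enrichment of looped genes
#' @param background_intensity Poisson intensity scale of the matrix
#'   background
#' @param chrom_bins number of matrix bins
#' @param bin_size matrix bin size (bp)
#' @param n_sc_genes,n_sc_cells UMI-matrix dimensions
#' @param n_flu_genes influenza genes appended to the catalogue
#' @param infected_fraction fraction of infected cells
#' @param degradation_multiplier median fold-increase of the degradation
#'   rate in infected cells (per-gene lognormal around this median)
#' @param degradation_sdlog lognormal spread of the per-gene multiplier
#' @return an object of class `synth_spec`
#' @export
synth_spec <- function(seed = 1L,
                       kinetics = kinetic_params(k_on = 2, burst_size = 25),
                       kind = "negative_binomial",
                       measurement = measurement_params(kappa = 2, a = 4,
                                                        mu_eps = 100,
                                                        sigma_eps = 20),
                       n_cells = 5000L, n_replicates = 2L,
                       condition = "tet40",
                       phase_weights = c(G1 = 0.5, S = 0.2, G2 = 0.3),
                       phase_multipliers = c(G1 = 1, S = 1, G2 = 1),
                       calib_counts = c(5, 10, 20, 50, 100, 200),
                       calib_cv = 0.1,
                       n_genes = 200L, looped_fraction = 0.3,
                       enrichment = 10, background_intensity = 5,
                       chrom_bins = 1000L, bin_size = 2000L,
                       n_sc_genes = 200L, n_sc_cells = 2000L,
                       n_flu_genes = 5L, infected_fraction = 0.4,
                       degradation_multiplier = 2,
                       degradation_sdlog = 0.5) {
  kind <- .match_kind(kind)
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate flow-FISH replicates with known truth
#'
#' Draws `X` from the chosen stationary model, `Y = eps + kappa X` with
#' skew-normal `eps`, and attaches trimodal DNA-content and lognormal FSC-A
#' channels correlated with the cell-cycle phase.
#'
#' @param spec a [synth_spec()]
#' @return list with `replicates` (list of [flowfish_dataset()]) and `truth`
#'   (spec parameters plus the per-cell latent counts)
#' @export
synth_flowfish <- function(spec) {
  .check(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  reps <- vector("list", spec$n_replicates)
  latents <- vector("list", spec$n_replicates)
  for (k in seq_len(spec$n_replicates)) {
    set.seed(sub_seed(spec$seed, 10L + k))
    n <- spec$n_cells
    phase <- sample(names(spec$phase_weights), n, replace = TRUE,
                    prob = spec$phase_weights)
    mult <- spec$phase_multipliers[phase]
    X <- integer(n)
    for (ph in unique(phase)) {
      idx <- which(phase == ph)
      kin <- spec$kinetics
      kin_ph <- if (spec$kind == "negative_binomial") {
        kinetic_params(k_on = kin$k_on,
                       burst_size = kin$burst_size * spec$phase_multipliers[ph])
      } else if (spec$kind == "poisson_beta") {
        kinetic_params(alpha = kin$alpha * spec$phase_multipliers[ph],
                       k_on = kin$k_on, k_off = kin$k_off)
      } else {
        kinetic_params(mu_X = kin$mu_X * spec$phase_multipliers[ph])
      }
      X[idx] <- sample_stationary(spec$kind, kin_ph, length(idx),
                                  seed = sub_seed(spec$seed,
                                                  1000L * k + match(ph, names(spec$phase_weights))))
    }
    set.seed(sub_seed(spec$seed, 20L + k))
    me <- spec$measurement
    eps <- rsn(n, me$a, me$mu_eps, me$sigma_eps)
    y <- eps + me$kappa * X
    # DNA content: 2N / S / 4N modes; FSC-A lognormal, larger in later phases
    dna_mean <- c(G1 = 1, S = 1.5, G2 = 2)[phase]
    dna_sd <- c(G1 = 0.07, S = 0.18, G2 = 0.09)[phase]
    dna <- rnorm(n, dna_mean, dna_sd)
    fsc <- rlnorm(n, meanlog = log(c(G1 = 1, S = 1.15, G2 = 1.3)[phase]),
                  sdlog = 0.2)
    reps[[k]] <- flowfish_dataset(y, replicate_id = k,
                                  condition = spec$condition,
                                  dna_content = dna, fsc_a = fsc)
    latents[[k]] <- list(X = X, phase = phase)
  }
  list(replicates = reps,
       truth = list(kind = spec$kind, kinetics = spec$kinetics,
                    measurement = spec$measurement, seed = spec$seed,
                    latent = latents))
}

#' Generate a background-only control dataset
#'
#' @param spec a [synth_spec()]
#' @param n_cells number of control cells (default `spec$n_cells`)
#' @return list with `values` (skew-normal draws) and `truth`
#' @export
synth_control <- function(spec, n_cells = spec$n_cells) {
  .check(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  set.seed(sub_seed(spec$seed, 30L))
  me <- spec$measurement
  list(values = rsn(n_cells, me$a, me$mu_eps, me$sigma_eps),
       truth = list(a = me$a, mu_eps = me$mu_eps, sigma_eps = me$sigma_eps,
                    seed = spec$seed))
}

#' Generate calibration (count, fluorescence) pairs
#'
#' Fluorescence is `kappa * count` with multiplicative gamma noise of
#' coefficient of variation `calib_cv` (zero noise gives the exact line).
#'
#' @param spec a [synth_spec()]
#' @param replicates_per_count repeated measures per grid point
#' @return data frame with columns `count`, `fluorescence`
#' @export
synth_calibration <- function(spec, replicates_per_count = 5L) {
  .check(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  set.seed(sub_seed(spec$seed, 40L))
  cnt <- rep(spec$calib_counts, each = replicates_per_count)
  mu <- spec$measurement$kappa * cnt
  y <- if (spec$calib_cv > 0) {
    shape <- 1 / spec$calib_cv^2
    rgamma(length(cnt), shape = shape, rate = shape / mu)
  } else mu
  data.frame(count = cnt, fluorescence = y)
}

#' Generate a binned interaction matrix and gene catalogue
#'
#' Poisson background counts with distance decay; genes flagged as looped
#' receive an `enrichment`-fold intensity at their TSS-TES bin pair.  The
#' catalogue deliberately contains duplicate-symbol and too-short genes to
#' exercise [filter_genes()].
#'
#' @param spec a [synth_spec()]
#' @return list with `matrix` ([interaction_matrix()]), `annotation`
#'   (refGene-style data frame incl. violations), `truth` (looping flags)
#' @export
synth_interaction_data <- function(spec) {
  .check(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  set.seed(sub_seed(spec$seed, 50L))
  nb <- spec$chrom_bins; bs <- spec$bin_size
  extent <- nb * bs
  G <- spec$n_genes
  # gene bodies: lengths 1-40 bins, uniform starts
  len <- pmax(round(rlnorm(G, log(6 * bs), 0.6)), bs + 500)
  len <- pmin(len, 40L * bs)
  start <- floor(runif(G, 0, extent - len - bs))
  strand <- sample(c("+", "-"), G, replace = TRUE)
  sym <- sprintf("SYNGENE%03d", seq_len(G))
  looped <- runif(G) < spec$looped_fraction
  ann <- data.frame(name = sym, chrom = "1", strand = strand,
                    txStart = start, txEnd = start + len,
                    stringsAsFactors = FALSE)
  # deliberate violations: a duplicated symbol pair and two short genes
  viol <- data.frame(
    name = c("SYNDUP", "SYNDUP", "SYNSHORT1", "SYNSHORT2"),
    chrom = "1", strand = "+",
    txStart = c(1e4, 5e4, 2e4, 3e4),
    txEnd = c(1e4 + 3 * bs, 5e4 + 3 * bs, 2e4 + bs %/% 2, 3e4 + bs %/% 3),
    stringsAsFactors = FALSE)
  annotation <- rbind(ann, viol)

  # background: sample pairs within a banded distance, Poisson counts with
  # 1/(1+distance_in_bins) decay
  max_band <- 50L
  ii <- rep(0:(nb - 1L), each = max_band + 1L)
  dd <- rep(0:max_band, nb)
  jj <- ii + dd
  keep <- jj < nb
  ii <- ii[keep]; jj <- jj[keep]; dd <- dd[keep]
  lam <- spec$background_intensity / (1 + dd)
  cnt <- rpois(length(ii), lam)
  nz <- cnt > 0
  ii <- ii[nz]; jj <- jj[nz]; cnt <- cnt[nz]
  # planted enrichment at looped genes' TSS-TES pairs
  tss <- ifelse(strand == "+", ann$txStart, ann$txEnd)
  tes <- ifelse(strand == "+", ann$txEnd, ann$txStart)
  bi <- floor(tss / bs); bj <- floor(tes / bs)
  dgene <- abs(bj - bi)
  extra_lam <- (spec$enrichment - 1) * spec$background_intensity /
    (1 + dgene)
  extra <- rpois(G, pmax(extra_lam, 0)) * looped
  add <- extra > 0
  mat <- interaction_matrix("1", bs,
                            bins_i = c(ii, pmin(bi, bj)[add]),
                            bins_j = c(jj, pmax(bi, bj)[add]),
                            counts = c(cnt, extra[add]), n_bins = nb)
  list(matrix = mat, annotation = annotation,
       truth = data.frame(symbol = sym, looped = looped,
                          stringsAsFactors = FALSE))
}

#' Generate a UMI count matrix with an infection structure
#'
#' Per-gene negative-binomial counts with gene-specific `(mu, k_on)`;
#' infected cells have every human gene's degradation rate raised by a
#' gene-specific lognormal multiplier, which lowers the dimensionless burst
#' frequency (and hence the mean) while leaving the burst size unchanged.
#' Influenza genes are expressed in infected cells only.
#'
#' @param spec a [synth_spec()]
#' @param mu_range lognormal parameters (meanlog, sdlog) of gene means
#' @param k_on_range lognormal parameters of gene burst frequencies
#' @param loop_effect optional data frame `(symbol, looped)`: looped genes
#'   get burst size scaled up and `k_on` down by `loop_strength` at fixed
#'   mean, mirroring the association under study
#' @param loop_strength fold-change applied to looped genes
#' @return list with `matrix` ([umi_matrix()]), `labels` (true infection
#'   status), `truth` (per-gene parameters per condition)
#' @export
synth_umi <- function(spec, mu_range = c(0, 1), k_on_range = c(-0.5, 0.8),
                      loop_effect = NULL, loop_strength = 4) {
  .check(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  set.seed(sub_seed(spec$seed, 60L))
  G <- spec$n_sc_genes; n <- spec$n_sc_cells
  sym <- sprintf("SYNGENE%03d", seq_len(G))
  mu <- rlnorm(G, mu_range[1], mu_range[2])
  k_on <- rlnorm(G, k_on_range[1], k_on_range[2])
  if (!is.null(loop_effect)) {
    idx <- match(sym, loop_effect$symbol)
    lo <- ifelse(!is.na(idx) & loop_effect$looped[idx], TRUE, FALSE)
    k_on[lo] <- k_on[lo] / loop_strength   # bigger bursts, rarer, same mean
  }
  flu <- if (spec$n_flu_genes > 0) sprintf("FLU%02d", seq_len(spec$n_flu_genes))
    else character(0)
  infected <- runif(n) < spec$infected_fraction
  rho <- rlnorm(G, log(spec$degradation_multiplier), spec$degradation_sdlog)
  counts <- matrix(0L, G + length(flu), n,
                   dimnames = list(c(sym, flu), sprintf("CELL%05d", seq_len(n))))
  for (g in seq_len(G)) {
    k_u <- k_on[g]; mu_u <- mu[g]
    k_i <- k_u / rho[g]; mu_i <- mu_u / rho[g]   # burst size unchanged
    x <- integer(n)
    x[!infected] <- rnbinom(sum(!infected), size = k_u, mu = mu_u)
    x[infected] <- rnbinom(sum(infected), size = k_i, mu = mu_i)
    counts[g, ] <- x
  }
  for (f in seq_along(flu)) {
    x <- integer(n)
    x[infected] <- rpois(sum(infected), 3)
    counts[length(sym) + f, ] <- x
  }
  m <- umi_matrix(counts, flu_genes = flu)
  list(matrix = m,
       labels = factor(ifelse(infected, "infected", "uninfected"),
                       levels = c("uninfected", "infected")),
       truth = data.frame(symbol = sym, mu_uninf = mu, k_on_uninf = k_on,
                          rho = rho, mu_inf = mu / rho, k_on_inf = k_on / rho,
                          stringsAsFactors = FALSE))
}
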