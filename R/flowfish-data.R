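#' A single flow-FISH replicate
#'
#' Per-cell fluorescence for one replicate of one condition, with optional
#' DNA-content and forward-scatter (FSC-A) channels used by the extrinsic
#' noise decomposition.
#'
#' @param fluorescence numeric vector of per-cell fluorescence (a.u.)
#' @param replicate_id replicate label
#' @param condition condition label (e.g. Tet dose in ng/mL)
#' @param dna_content optional per-cell DNA-content channel (same length)
#' @param fsc_a optional per-cell FSC-A channel (same length)
#' @return an object of class `flowfish_dataset`
#' @export
flowfish_dataset <- function(fluorescence, replicate_id = 1L,
                             condition = "default", dna_content = NULL,
                             fsc_a = NULL) {
  .check(is.numeric(fluorescence) && length(fluorescence) >= 1,
         "fluorescence must be a non-empty numeric vector")
  .check(all(is.finite(fluorescence)), "fluorescence values must be finite")
  n <- length(fluorescence)
  for (ch in list(dna_content = dna_content, fsc_a = fsc_a)) NULL
  if (!is.null(dna_content))
    .check(length(dna_content) == n, "dna_content length mismatch")
  if (!is.null(fsc_a))
    .check(length(fsc_a) == n, "fsc_a length mismatch")
  structure(list(fluorescence = as.double(fluorescence),
                 replicate_id = replicate_id, condition = condition,
                 dna_content = dna_content, fsc_a = fsc_a),
            class = "flowfish_dataset")
}

#' @export
print.flowfish_dataset <- function(x, ...) {
  cat(sprintf(
    "flow-FISH replicate %s, condition %s: %d cells%s%s\n",
    x$replicate_id, x$condition, length(x$fluorescence),
    if (!is.null(x$dna_content)) " +DNA" else "",
    if (!is.null(x$fsc_a)) " +FSC-A" else ""))
  invisible(x)
}

# Bin per-cell values into a weighted grid to speed up repeated likelihood
# evaluation; bin width is far below the background scale so the
# approximation error is negligible.
.bin_values <- function(y, n_bins) {
  if (length(y) <= n_bins) return(list(y = y, w = rep(1, length(y))))
  br <- seq(min(y), max(y), length.out = n_bins + 1L)
  idx <- findInterval(y, br, rightmost.closed = TRUE)
  cnt <- tabulate(idx, nbins = n_bins)
  keep <- cnt > 0L
  mid <- (br[-1L] + br[-length(br)]) / 2
  list(y = mid[keep], w = as.double(cnt[keep]))
}

# log-pmf table for the chosen kind at given kinetic values; errors if the
# truncated support fails to capture the mass (diagnostic included)
.logpmf_table <- function(kind, kin, n_nodes = 96L) {
  if (kind == "poisson_beta") {
    mu <- kin[["mu_X"]]; k_on <- kin[["k_on"]]; k_off <- kin[["k_off"]]
    alpha <- mu * (k_on + k_off) / k_on
    cv2 <- 1 / mu + k_off / (k_on * (k_on + k_off + 1))
    xmax <- support_bound(mu, cv2)
    lp <- .pb_logpmf_table(alpha, k_on, k_off, xmax, n_nodes)
  } else if (kind == "negative_binomial") {
    mu <- kin[["mu_X"]]; k_on <- kin[["k_on"]]
    xmax <- max(10L, qnbinom(1 - 1e-10, size = k_on, mu = mu) + 5L)
    lp <- dnbinom(0:xmax, size = k_on, mu = mu, log = TRUE)
  } else {
    mu <- kin[["mu_X"]]
    xmax <- max(10L, qpois(1 - 1e-12, mu) + 5L)
    lp <- dpois(0:xmax, mu, log = TRUE)
  }
  mass <- sum(exp(lp))
  if (!is.finite(mass) || mass < 1 - 1e-6) {
    stop(sprintf(
      "truncated pmf captures only %.8f of the mass at xmax = %d (kind %s)",
      mass, length(lp) - 1L, kind), call. = FALSE)
  }
  lp
}

#' Log-likelihood of fluorescence under the measurement equation
#'
#' Marginal log-density of `Y = eps + kappa X` where `X` follows the chosen
#' stationary model and `eps` the skew-normal background: a truncated sum
#' `log sum_x pmf(x) f_eps(y - kappa x)`.
#'
#' @param y numeric vector of fluorescence values (a.u.)
#' @param kinetics a [kinetic_params()] object
#' @param meas a [measurement_params()] object
#' @param kind model kind (see [model_kinds()])
#' @return numeric vector of per-cell log densities
#' @export
fluorescence_loglik <- function(y, kinetics, meas, kind = "negative_binomial") {
  kind <- .match_kind(kind)
  .check(inherits(meas, "measurement_params"), "meas must be measurement_params")
  kin <- c(mu_X = kinetics$mu_X, k_on = kinetics$k_on, k_off = kinetics$k_off)
  lp <- .logpmf_table(kind, kin)
  .sn_conv_logdens(y, lp, meas$kappa, meas$a, meas$mu_eps, meas$sigma_eps)
}
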