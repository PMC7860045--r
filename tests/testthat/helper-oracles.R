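# Independent oracles shared across tests.  Everything here is deliberately
# naive (direct Monte Carlo, enumeration) and never calls the code path it
# is used to check.

# Monte-Carlo moments of the Poisson-beta mixture via the raw hierarchy
mc_pb_moments <- function(alpha, k_on, k_off, n = 1e5, seed = 1) {
  set.seed(seed)
  x <- rpois(n, alpha * rbeta(n, k_on, k_off))
  list(mu = mean(x), cv2 = var(x) / mean(x)^2,
       se_mu = sd(x) / sqrt(n))
}

# Monte-Carlo pmf of the Poisson-beta mixture on 0..xmax
mc_pb_pmf <- function(alpha, k_on, k_off, xmax, n = 1e6, seed = 1) {
  set.seed(seed)
  x <- rpois(n, alpha * rbeta(n, k_on, k_off))
  tabulate(x + 1L, nbins = xmax + 1L) / n
}

# brute-force HPD by enumerating every contiguous window
enum_hpd <- function(draws, mass) {
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- c(x[1], x[k]); bw <- x[k] - x[1]
  for (i in seq_len(n - k + 1L)) {
    w <- x[i + k - 1L] - x[i]
    if (w < bw - 1e-12) { bw <- w; best <- c(x[i], x[i + k - 1L]) }
  }
  best
}

# law of total variance by hand on grouped values
hand_decompose <- function(means, vars, weights) {
  w <- weights / sum(weights)
  m <- sum(w * means)
  ext <- sum(w * (means - m)^2)
  int <- sum(w * vars)
  c(extrinsic = ext / (ext + int), intrinsic = int / (ext + int))
}

# quick synthetic flow-FISH replicate without going through synth_spec
quick_flowfish <- function(n, k_on, b, kappa, a, mu_eps, sigma_eps, seed) {
  set.seed(seed)
  x <- rnbinom(n, size = k_on, mu = k_on * b)
  eps <- rsn(n, a, mu_eps, sigma_eps)
  flowfish_dataset(eps + kappa * x)
}
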