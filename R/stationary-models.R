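#' @title Stationary distributions of the phenomenological expression models
#' @name stationary_models
#' @description
#' Three nested models for the stationary per-cell mRNA count `X`:
#' the two-state (telegraph) model whose stationary law is a Poisson-beta
#' mixture `X | P ~ Poi(alpha * P)`, `P ~ Beta(k_on, k_off)`; its bursting
#' limit (`alpha, k_off -> Inf` at fixed burst size `b = alpha/k_off`), a
#' negative binomial with mean `k_on * b` and shape `k_on`; and the Poisson
#' model of unregulated expression with mean `mu_X`.
NULL

# Gauss-Jacobi rule for int_0^1 g(p) Beta(p; k_on, k_off) dp.
# statmod supplies nodes/weights for weight (1-x)^a (1+x)^b on [-1,1]
# with a = k_off - 1, b = k_on - 1; mapping p = (x+1)/2 and dividing by
# B(k_on, k_off) yields probability weights that sum to 1 exactly.
.beta_quad <- function(k_on, k_off, n_nodes) {
  gq <- statmod::gauss.quad(n_nodes, kind = "jacobi",
                            alpha = k_off - 1, beta = k_on - 1)
  logw <- log(gq$weights) - (k_on + k_off - 1) * log(2) - lbeta(k_on, k_off)
  list(p = (gq$nodes + 1) / 2, logw = logw)
}

# log pmf table of the Poisson-beta distribution for x = 0..xmax with a
# fixed quadrature rule (log-sum-exp across nodes, stable at large alpha)
.pb_logpmf_table <- function(alpha, k_on, k_off, xmax, n_nodes = 96L) {
  q <- .beta_quad(k_on, k_off, n_nodes)
  x <- 0:xmax
  lam <- alpha * q$p                       # length n_nodes
  # matrix (x, node): x*log(lam) - lam - lgamma(x+1) + logw
  loglam <- log(lam)
  m <- outer(x, loglam) - rep(lam, each = length(x)) - lgamma(x + 1) +
    rep(q$logw, each = length(x))
  mx <- apply(m, 1L, max)
  lp <- mx + log(rowSums(exp(m - mx)))
  lp[!is.finite(mx)] <- -Inf
  lp
}

#' Adaptive support bound for truncated summations
#'
#' Upper count bound `mu + 20 sqrt(mu (1 + CV2 mu))`, generously covering
#' all probability mass of the stationary laws at testable cost.
#' @param mu mean count
#' @param cv2 squared coefficient of variation
#' @return integer bound (at least 10)
#' @export
support_bound <- function(mu, cv2) {
  max(10L, as.integer(ceiling(mu + 20 * sqrt(mu * (1 + cv2 * mu)))))
}

#' Poisson-beta probability mass function
#'
#' Stationary law of the telegraph model: `X | P ~ Poi(alpha P)` with
#' `P ~ Beta(k_on, k_off)`.  Computed by Gauss-Jacobi quadrature against the
#' beta weight (exact for the endpoint singularities when `k_on < 1` or
#' `k_off < 1`), with the node count doubled until successive rules agree
#' within `tol`.
#'
#' @param x vector of non-negative integer counts
#' @param p a [kinetic_params()] object with `alpha`, `k_on`, `k_off`
#' @param tol absolute convergence tolerance of the node-doubling loop
#' @param log if `TRUE` return log probabilities
#' @return numeric vector of probabilities (values in `[0, 1]`)
#' @examples
#' poisson_beta_pmf(0, kinetic_params(alpha = 1, k_on = 1, k_off = 1))
#' # = 1 - exp(-1)
#' @export
poisson_beta_pmf <- function(x, p, tol = 1e-10, log = FALSE) {
  .check(inherits(p, "kinetic_params"), "p must be kinetic_params")
  .check(!is.null(p$alpha) && !is.null(p$k_on) && !is.null(p$k_off),
         "poisson_beta_pmf needs alpha, k_on and k_off")
  .check(all(is.finite(x)) && all(x >= 0) && all(x == floor(x)),
         "x must be non-negative integers")
  xmax <- max(x)
  n <- 32L
  lp_old <- .pb_logpmf_table(p$alpha, p$k_on, p$k_off, xmax, n)
  repeat {
    n <- n * 2L
    lp_new <- .pb_logpmf_table(p$alpha, p$k_on, p$k_off, xmax, n)
    if (max(abs(exp(lp_new) - exp(lp_old))) < tol || n >= 2048L) break
    lp_old <- lp_new
  }
  out <- lp_new[x + 1L]
  if (log) out else exp(out)
}

#' Mean and noise of the Poisson-beta model
#'
#' The stationary mean is `mu_X = alpha k_on / (k_on + k_off)`; the squared
#' coefficient of variation follows from the law of total variance over the
#' beta mixing variable:
#' `CV2_X = 1/mu_X + k_off / (k_on (k_on + k_off + 1))`.
#'
#' @param p a [kinetic_params()] object with `alpha`, `k_on`, `k_off`
#' @return named list with `mu_X` and `CV2_X`
#' @export
poisson_beta_moments <- function(p) {
  .check(inherits(p, "kinetic_params"), "p must be kinetic_params")
  .check(!is.null(p$alpha) && !is.null(p$k_on) && !is.null(p$k_off),
         "poisson_beta_moments needs alpha, k_on and k_off")
  s <- p$k_on + p$k_off
  mu <- p$alpha * p$k_on / s
  cv2 <- 1 / mu + p$k_off / (p$k_on * (s + 1))
  list(mu_X = mu, CV2_X = cv2)
}

#' Negative-binomial probability mass function (bursting limit)
#'
#' Gamma-Poisson mixture with burst frequency `k_on` (gamma shape) and burst
#' size `b`; mean `k_on * b`, `CV2 = 1/mu + 1/k_on`.
#'
#' @param x vector of non-negative integer counts
#' @param k_on burst frequency (> 0)
#' @param b average burst size (> 0)
#' @param log if `TRUE` return log probabilities
#' @return numeric vector of probabilities
#' @export
negbin_pmf <- function(x, k_on, b, log = FALSE) {
  .check(is.numeric(k_on) && k_on > 0 && is.finite(k_on), "k_on must be > 0")
  .check(is.numeric(b) && b > 0 && is.finite(b), "b must be > 0")
  .check(all(is.finite(x)) && all(x >= 0) && all(x == floor(x)),
         "x must be non-negative integers")
  dnbinom(x, size = k_on, mu = k_on * b, log = log)
}

#' Negative-binomial mean and noise
#' @inheritParams negbin_pmf
#' @return named list with `mu_X` and `CV2_X = 1/mu_X + 1/k_on`
#' @export
negbin_moments <- function(k_on, b) {
  mu <- k_on * b
  list(mu_X = mu, CV2_X = 1 / mu + 1 / k_on)
}

#' Poisson probability mass function (unregulated expression)
#'
#' @param x vector of non-negative integer counts
#' @param mu_X mean count (>= 0; `mu_X = 0` is the degenerate point mass at 0)
#' @param log if `TRUE` return log probabilities
#' @return numeric vector of probabilities
#' @export
poisson_pmf <- function(x, mu_X, log = FALSE) {
  .check(is.numeric(mu_X) && length(mu_X) == 1L && is.finite(mu_X) &&
           mu_X >= 0, "mu_X must be a single finite number >= 0")
  .check(all(is.finite(x)) && all(x >= 0) && all(x == floor(x)),
         "x must be non-negative integers")
  dpois(x, mu_X, log = log)
}

#' Draw i.i.d. stationary mRNA counts via the exact mixture hierarchy
#'
#' @param kind one of `"poisson_beta"`, `"negative_binomial"`, `"poisson"`
#' @param p a [kinetic_params()] object carrying the parameters the chosen
#'   model needs
#' @param n number of draws (>= 1)
#' @param seed integer seed; the draw is reproducible given the seed
#' @return integer vector of length `n`
#' @export
sample_stationary <- function(kind, p, n, seed) {
  kind <- .match_kind(kind)
  .check(inherits(p, "kinetic_params"), "p must be kinetic_params")
  .check(is.numeric(n) && n >= 1, "n must be >= 1")
  set.seed(seed)
  switch(kind,
    poisson_beta = {
      .check(!is.null(p$alpha) && !is.null(p$k_on) && !is.null(p$k_off),
             "poisson_beta sampling needs alpha, k_on, k_off")
      rpois(n, p$alpha * rbeta(n, p$k_on, p$k_off))
    },
    negative_binomial = {
      .check(!is.null(p$k_on) && !is.null(p$burst_size),
             "negative_binomial sampling needs k_on and burst_size")
      rnbinom(n, size = p$k_on, mu = p$k_on * p$burst_size)
    },
    poisson = {
      .check(!is.null(p$mu_X), "poisson sampling needs mu_X")
      rpois(n, p$mu_X)
    })
}

#' Model pmf over a truncated support, for any of the three kinds
#'
#' @inheritParams sample_stationary
#' @param xmax upper support bound; defaults to [support_bound()] at the
#'   model's own moments
#' @return numeric vector of probabilities for `x = 0..xmax`
#' @export
stationary_pmf <- function(kind, p, xmax = NULL) {
  kind <- .match_kind(kind)
  mo <- stationary_moments(kind, p)
  if (is.null(xmax)) xmax <- support_bound(mo$mu_X, mo$CV2_X)
  x <- 0:xmax
  switch(kind,
    poisson_beta = poisson_beta_pmf(x, p),
    negative_binomial = negbin_pmf(x, p$k_on, p$burst_size),
    poisson = poisson_pmf(x, p$mu_X))
}

#' Moments for any of the three kinds
#' @inheritParams sample_stationary
#' @return named list with `mu_X` and `CV2_X`
#' @export
stationary_moments <- function(kind, p) {
  kind <- .match_kind(kind)
  switch(kind,
    poisson_beta = poisson_beta_moments(p),
    negative_binomial = negbin_moments(p$k_on, p$burst_size),
    poisson = list(mu_X = p$mu_X, CV2_X = 1 / p$mu_X))
}

#' Total-variation distance between two pmf vectors on a common support
#' @param p1,p2 probability vectors of equal length
#' @return `0.5 * sum(|p1 - p2|)`
#' @export
tv_distance <- function(p1, p2) {
  .check(length(p1) == length(p2), "pmf vectors must have equal length")
  0.5 * sum(abs(p1 - p2))
}
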