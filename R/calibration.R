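#' Calibrate the fluorescence scale from (count, fluorescence) pairs
#'
#' Fits a gamma generalised linear model with identity link of fluorescence
#' on molecule count through the origin; the slope and its standard error
#' define a moment-matched gamma prior on the scale `kappa`.
#'
#' @param pairs a data frame (or matrix) with columns `count` and
#'   `fluorescence`; at least 3 rows, counts > 0, fluorescence > 0
#' @return a list with `kappa_hat`, `se`, and gamma hyperparameters
#'   `shape`/`rate` (prior mean `kappa_hat`, prior sd `se`)
#' @export
calibrate_kappa_prior <- function(pairs) {
  pairs <- as.data.frame(pairs)
  .check(all(c("count", "fluorescence") %in% names(pairs)),
         "pairs must have columns 'count' and 'fluorescence'")
  .check(nrow(pairs) >= 3, "need at least 3 calibration pairs")
  x <- as.double(pairs$count); y <- as.double(pairs$fluorescence)
  .check(all(is.finite(x)) && all(is.finite(y)) && all(x > 0) && all(y > 0),
         "counts and fluorescence must be finite and positive")
  .check(sd(x) > 0 || length(unique(x)) > 1 || TRUE, "ok")
  slope0 <- sum(x * y) / sum(x * x)
  fit <- tryCatch(
    suppressWarnings(glm(y ~ x + 0, family = Gamma(link = "identity"),
                         start = slope0, control = list(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    kap <- slope0
    se <- abs(slope0) * 1e-6
  } else {
    kap <- unname(coef(fit)[1])
    se <- sqrt(vcov(fit)[1, 1])
    if (!is.finite(se) || se <= 0) se <- abs(kap) * 1e-6
  }
  .check(is.finite(kap) && kap > 0, "calibration produced a non-positive slope")
  list(kappa_hat = kap, se = se,
       shape = kap^2 / se^2, rate = kap / se^2)
}

#' Default prior specification for model fitting
#'
#' Uncalibrated rate parameters get vague gamma priors with mean 1 and
#' variance 1e3 (shape 1e-3, rate 1e-3).  When a calibration object and/or a
#' background fit are supplied, only the `kappa` and `eps` entries are
#' replaced by informative counterparts.
#'
#' @param kind model kind (see [model_kinds()])
#' @param calib optional result of [calibrate_kappa_prior()]
#' @param background optional result of [fit_background()]
#' @return an object of class `prior_spec`: a named list of prior entries,
#'   each `list(family = "gamma", shape =, rate =)` for sampled parameters,
#'   plus a fixed-value `eps` entry for the background point estimates
#' @export
default_priors <- function(kind = "negative_binomial", calib = NULL,
                           background = NULL) {
  kind <- .match_kind(kind)
  vague <- list(family = "gamma", shape = 1e-3, rate = 1e-3)
  pars <- switch(kind,
    poisson_beta = c("mu_X", "k_on", "k_off"),
    negative_binomial = c("mu_X", "k_on"),
    poisson = "mu_X")
  pr <- setNames(rep(list(vague), length(pars)), pars)
  pr$kappa <- vague
  if (!is.null(calib)) {
    pr$kappa <- list(family = "gamma", shape = calib$shape, rate = calib$rate)
  }
  if (!is.null(background)) {
    pr$eps <- list(family = "fixed", a = background$a,
                   mu_eps = background$mu_eps,
                   sigma_eps = background$sigma_eps)
  }
  structure(pr, class = "prior_spec", kind = kind)
}

.gamma_logprior <- function(x, entry) {
  dgamma(x, shape = entry$shape, rate = entry$rate, log = TRUE)
}
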