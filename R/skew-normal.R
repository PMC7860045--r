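#' Skew-normal background model for flow-FISH fluorescence
#'
#' The background (unspecific staining plus auto-fluorescence) of control
#' cells is modelled with Azzalini's skew-normal distribution in the standard
#' location/scale form
#' `f(y) = (2/omega) * phi(z) * Phi(a z)`, `z = (y - xi)/omega`,
#' with location `xi` (`mu_eps`), scale `omega` (`sigma_eps`) and skewness
#' `a`.
#'
#' @param y numeric vector of fluorescence values
#' @param a skewness parameter (real; `a = 0` gives the normal density)
#' @param mu_eps location parameter (a.u.)
#' @param sigma_eps scale parameter (a.u., > 0)
#' @param log if `TRUE` return log densities
#' @return densities at `y`
#' @export
dsn <- function(y, a, mu_eps, sigma_eps, log = FALSE) {
  .check(sigma_eps > 0, "sigma_eps must be > 0")
  z <- (y - mu_eps) / sigma_eps
  ld <- log(2) - log(sigma_eps) + dnorm(z, log = TRUE) +
    pnorm(a * z, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' @rdname dsn
#' @param n number of draws
#' @return `rsn`: numeric vector of skew-normal draws (uses R's RNG stream)
#' @export
rsn <- function(n, a, mu_eps, sigma_eps) {
  .check(sigma_eps > 0, "sigma_eps must be > 0")
  delta <- a / sqrt(1 + a^2)
  u0 <- abs(rnorm(n))
  u1 <- rnorm(n)
  mu_eps + sigma_eps * (delta * u0 + sqrt(1 - delta^2) * u1)
}

#' Mean and standard deviation implied by skew-normal parameters
#' @inheritParams dsn
#' @return named list with `mean` and `sd`
#' @export
sn_moments <- function(a, mu_eps, sigma_eps) {
  delta <- a / sqrt(1 + a^2)
  m <- mu_eps + sigma_eps * delta * sqrt(2 / pi)
  v <- sigma_eps^2 * (1 - 2 * delta^2 / pi)
  list(mean = m, sd = sqrt(v))
}

# method-of-moments starting values: invert the skewness equation
.sn_mom_start <- function(y) {
  m <- mean(y); s <- sd(y)
  g1 <- mean((y - m)^3) / s^3
  # clamp to the attainable skewness range of the skew normal (~0.995)
  g1 <- max(min(g1, 0.95), -0.95)
  r <- (2 * abs(g1) / (4 - pi))^(1 / 3)
  delta <- sign(g1) * r / sqrt(2 / pi * (1 + r^2))
  delta <- max(min(delta, 0.99), -0.99)
  a <- delta / sqrt(1 - delta^2)
  omega <- s / sqrt(1 - 2 * delta^2 / pi)
  xi <- m - omega * delta * sqrt(2 / pi)
  c(a = a, mu_eps = xi, sigma_eps = omega)
}

#' Fit the skew-normal background to control-cell fluorescence
#'
#' Maximum-likelihood point estimates of `(a, mu_eps, sigma_eps)` from a
#' background-only (control line) sample, initialised by method of moments.
#'
#' @param control_values numeric vector of control-cell fluorescence
#'   (length >= 30)
#' @return a named list with elements `a`, `mu_eps`, `sigma_eps`, the
#'   maximised `loglik`, and the implied `mean`/`sd`
#' @export
fit_background <- function(control_values) {
  y <- control_values[is.finite(control_values)]
  .check(length(y) >= 30, "need at least 30 finite control values")
  .check(sd(y) > 0, "control values are constant; cannot fit a background")
  start <- .sn_mom_start(y)
  nll <- function(th) {
    s <- exp(th[3])
    -sum(dsn(y, th[1], th[2], s, log = TRUE))
  }
  fit <- optim(c(start[1], start[2], log(start[3])), nll,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  out <- list(a = fit$par[1], mu_eps = fit$par[2],
              sigma_eps = exp(fit$par[3]), loglik = -fit$value)
  mo <- sn_moments(out$a, out$mu_eps, out$sigma_eps)
  out$mean <- mo$mean
  out$sd <- mo$sd
  out
}

#' Measurement parameters of one flow-FISH replicate
#'
#' @param kappa fluorescence scale in a.u. per molecule (> 0)
#' @param a,mu_eps,sigma_eps skew-normal background parameters (see [dsn()])
#' @return an object of class `measurement_params`
#' @export
measurement_params <- function(kappa, a, mu_eps, sigma_eps) {
  .check(is.finite(kappa) && kappa > 0, "kappa must be > 0")
  .check(is.finite(sigma_eps) && sigma_eps > 0, "sigma_eps must be > 0")
  .check(is.finite(a) && is.finite(mu_eps), "a and mu_eps must be finite")
  structure(list(kappa = kappa, a = a, mu_eps = mu_eps,
                 sigma_eps = sigma_eps),
            class = "measurement_params")
}
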