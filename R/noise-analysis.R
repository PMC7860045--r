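#' @title Noise-versus-mean analysis
#' @name noise_analysis
#' @description
#' Fits the noise curve `CV2 = A / mu + B` by orthogonal-distance regression
#' in log-log coordinates, measures each gene's log-scale vertical distance
#' `nu` from the negative-binomial reference curve
#' `CV2 = 1/mu + 1/k_on_bar`, classifies genes into low / intermediate /
#' high noise groups, and tests association between noise and interaction
#' scores.
NULL

#' Orthogonal-distance regression of the noise curve
#'
#' Minimises the summed squared perpendicular distances of the points to the
#' curve `CV2 = A/mu + B`, by default in log-log coordinates (matching the
#' log-scaled noise plots); set `loglog = FALSE` for plain-space ODR.
#'
#' @param mu vector of mean expressions (> 0, length >= 3)
#' @param cv2 vector of squared coefficients of variation (> 0)
#' @param loglog fit in log-log coordinates (default `TRUE`)
#' @return an object of class `noise_fit`: list with `A`, `B`, `residual`
#'   (objective at the optimum) and `n`
#' @export
odr_noise_fit <- function(mu, cv2, loglog = TRUE) {
  .check(length(mu) == length(cv2), "mu and cv2 lengths differ")
  .check(length(mu) >= 3, "need at least 3 points")
  .check(all(is.finite(mu)) && all(is.finite(cv2)) && all(mu > 0) &&
           all(cv2 > 0), "mu and cv2 must be finite and positive")
  if (loglog) {
    u <- log(mu); v <- log(cv2)
    # distance of (u0, v0) to the curve v = log(A exp(-u) + B)
    dist2 <- function(u0, v0, A, B) {
      g <- function(t) (u0 - t)^2 + (v0 - log(A * exp(-t) + B))^2
      optimize(g, interval = c(u0 - 12, u0 + 12))$objective
    }
    obj <- function(th) {
      A <- exp(th[1]); B <- exp(th[2])
      sum(vapply(seq_along(u), function(i) dist2(u[i], v[i], A, B), 0))
    }
  } else {
    dist2 <- function(x0, y0, A, B) {
      g <- function(t) (x0 - t)^2 + (y0 - (A / t + B))^2
      lo <- max(x0 / 50, 1e-12)
      optimize(g, interval = c(lo, x0 * 50))$objective
    }
    obj <- function(th) {
      A <- exp(th[1]); B <- exp(th[2])
      sum(vapply(seq_along(mu), function(i) dist2(mu[i], cv2[i], A, B), 0))
    }
  }
  # start from the ordinary regression of cv2 on 1/mu
  st <- coef(lm(cv2 ~ I(1 / mu)))
  A0 <- max(st[2], 1e-6); B0 <- max(st[1], 1e-6)
  fit <- optim(c(log(A0), log(B0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  structure(list(A = exp(fit$par[1]), B = exp(fit$par[2]),
                 residual = fit$value, n = length(mu), loglog = loglog),
            class = "noise_fit")
}

#' @export
print.noise_fit <- function(x, ...) {
  cat(sprintf("noise curve CV2 = A/mu + B: A = %.4g, B = %.4g (%s ODR, n = %d)\n",
              x$A, x$B, if (x$loglog) "log-log" else "plain", x$n))
  invisible(x)
}

#' Negative-binomial reference noise curve
#'
#' `CV2 = 1/mu + 1/k_on_bar`; with `k_on_bar = Inf` this is the Poisson
#' curve `1/mu`.
#'
#' @param mu mean expression (> 0)
#' @param k_on_bar sample-average burst frequency (> 0, may be `Inf`)
#' @return predicted CV2
#' @export
reference_curve <- function(mu, k_on_bar) {
  .check(all(mu > 0), "mu must be > 0")
  .check(all(k_on_bar > 0), "k_on_bar must be > 0")
  1 / mu + 1 / k_on_bar
}

#' Log-scale vertical distance from the reference curve
#'
#' `nu = log(CV2) - log(1/mu + 1/k_on_bar)` in natural logarithm: a gene on
#' the curve has `nu = 0`, a gene with CV2 `e`-fold above it has `nu = 1`.
#'
#' @param mu mean expression (> 0)
#' @param cv2 observed CV2 (> 0)
#' @param k_on_bar sample-average burst frequency of the reference curve
#' @param base logarithm base (natural by default)
#' @return the distance `nu` (vectorised)
#' @export
nu_distance <- function(mu, cv2, k_on_bar, base = exp(1)) {
  .check(all(cv2 > 0), "cv2 must be > 0")
  (log(cv2) - log(reference_curve(mu, k_on_bar))) / log(base)
}

#' Three-group noise classification
#'
#' `low` for `nu <= 0`, `intermediate` for `0 < nu <= nu1`, `high` for
#' `nu > nu1`; the boundary `nu = nu1` is assigned to the intermediate
#' group.
#'
#' @param nu vector of distances
#' @param nu1 threshold separating intermediate from high noise
#'   (default 4.5)
#' @return factor with levels `low`, `intermediate`, `high`
#' @export
classify_noise <- function(nu, nu1 = 4.5) {
  .check(all(is.finite(nu)), "nu must be finite")
  factor(ifelse(nu <= 0, "low", ifelse(nu <= nu1, "intermediate", "high")),
         levels = c("low", "intermediate", "high"))
}

#' One-sided Mann-Whitney tests between noise groups
#'
#' Tests whether interaction scores in the higher-noise group stochastically
#' dominate the next group down: high vs intermediate and intermediate vs
#' low.  Uses the normal approximation with tie correction for groups above
#' 50 observations.
#'
#' @param scores numeric vector of interaction scores
#' @param groups factor from [classify_noise()] (same length)
#' @return data frame with columns `comparison`, `U`, `p_value`, `n1`, `n2`
#' @export
group_score_test <- function(scores, groups) {
  .check(length(scores) == length(groups), "lengths differ")
  g <- factor(groups, levels = c("low", "intermediate", "high"))
  cmp <- list(c("high", "intermediate"), c("intermediate", "low"))
  rows <- lapply(cmp, function(cc) {
    x <- scores[g == cc[1]]; y <- scores[g == cc[2]]
    .check(length(x) > 0 && length(y) > 0,
           "group of size 0 in comparison %s vs %s", cc[1], cc[2])
    exact <- length(x) <= 50 && length(y) <= 50
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "greater", exact = exact))
    data.frame(comparison = paste(cc[1], ">", cc[2]),
               U = unname(wt$statistic), p_value = wt$p.value,
               n1 = length(x), n2 = length(y))
  })
  do.call(rbind, rows)
}

#' Ordinary least-squares association between score and a kinetic quantity
#'
#' @param x interaction scores (>= 3 values with non-zero variance)
#' @param y response (e.g. `nu`, `k_on`, burst size)
#' @return list with `slope`, `p_value` (two-sided t-test on the slope),
#'   `sign`, and the underlying `lm` fit
#' @export
linear_association <- function(x, y) {
  .check(length(x) == length(y) && length(x) >= 3,
         "need at least 3 paired values")
  .check(sd(x) > 0, "zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["x", "Estimate"]),
       p_value = unname(sm["x", "Pr(>|t|)"]),
       sign = sign(unname(sm["x", "Estimate"])), fit = fit)
}
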