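#' Kinetic parameters of the two-state (telegraph) expression models
#'
#' Bundles the dimensionless bursting rates of the stationary models: the
#' transcription rate `alpha`, the switch rates `k_on` and `k_off` (all in
#' units of the mRNA degradation rate `d_tilde`), together with the derived
#' burst size `b = alpha / k_off` and mean expression `mu_X`.  Whichever of
#' `{alpha, k_off}` versus `{burst_size}` is supplied, the other is derived
#' consistently; for the negative-binomial regime only `(k_on, burst_size)`
#' (or `(mu_X, k_on)`) are meaningful.
#'
#' @param alpha dimensionless transcription rate (> 0)
#' @param k_on dimensionless "off -> on" switch rate (> 0)
#' @param k_off dimensionless "on -> off" switch rate (> 0)
#' @param burst_size average burst size `alpha / k_off`
#' @param mu_X mean mRNA count; for the Poisson model this is the only
#'   required parameter
#' @param d_tilde optional mRNA degradation rate in 1/min used by
#'   [rescale_rates()]
#' @return an object of class `kinetic_params`
#' @examples
#' kinetic_params(alpha = 10, k_on = 1, k_off = 1)
#' kinetic_params(k_on = 2, burst_size = 25)
#' @export
kinetic_params <- function(alpha = NULL, k_on = NULL, k_off = NULL,
                           burst_size = NULL, mu_X = NULL, d_tilde = NULL) {
  num1 <- function(x, nm) {
    if (is.null(x)) return(NULL)
    .check(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0,
           "%s must be a single finite positive number", nm)
    as.double(x)
  }
  alpha <- num1(alpha, "alpha"); k_on <- num1(k_on, "k_on")
  k_off <- num1(k_off, "k_off"); burst_size <- num1(burst_size, "burst_size")
  mu_X <- num1(mu_X, "mu_X"); d_tilde <- num1(d_tilde, "d_tilde")

  if (!is.null(alpha) && !is.null(k_off)) {
    b <- alpha / k_off
    .check(is.null(burst_size) || abs(burst_size - b) < 1e-8 * b,
           "burst_size inconsistent with alpha / k_off")
    burst_size <- b
  } else if (!is.null(burst_size)) {
    if (!is.null(k_off)) alpha <- burst_size * k_off
    if (!is.null(alpha) && is.null(k_off)) k_off <- alpha / burst_size
  }
  if (is.null(mu_X)) {
    if (!is.null(alpha) && !is.null(k_on) && !is.null(k_off)) {
      mu_X <- alpha * k_on / (k_on + k_off)
    } else if (!is.null(k_on) && !is.null(burst_size)) {
      mu_X <- k_on * burst_size
    }
  } else if (!is.null(k_on) && is.null(burst_size) && is.null(alpha)) {
    # negative-binomial style (mu_X, k_on) parametrisation
    burst_size <- mu_X / k_on
  }
  structure(list(alpha = alpha, k_on = k_on, k_off = k_off,
                 burst_size = burst_size, mu_X = mu_X, d_tilde = d_tilde),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (dimensionless, units of d_tilde):\n")
  for (nm in names(x)) if (!is.null(x[[nm]]))
    cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Convert dimensionless rates to per-minute rates
#'
#' The dimensionless rates are expressed in units of the inverse mean mRNA
#' lifetime; multiplying by the degradation rate `d_tilde` (1/min) restores
#' physical units, e.g. `k_off_tilde = k_off * d_tilde`.
#'
#' @param p a [kinetic_params()] object
#' @param d_tilde degradation rate in 1/min; defaults to `p$d_tilde`
#' @return a named list of per-minute rates (`alpha_tilde`, `k_on_tilde`,
#'   `k_off_tilde`, `d_tilde`); entries absent from `p` are omitted
#' @export
rescale_rates <- function(p, d_tilde = p$d_tilde) {
  .check(inherits(p, "kinetic_params"), "p must be kinetic_params")
  .check(!is.null(d_tilde) && is.finite(d_tilde) && d_tilde > 0,
         "d_tilde must be supplied and positive")
  out <- list(d_tilde = d_tilde)
  if (!is.null(p$alpha)) out$alpha_tilde <- p$alpha * d_tilde
  if (!is.null(p$k_on)) out$k_on_tilde <- p$k_on * d_tilde
  if (!is.null(p$k_off)) out$k_off_tilde <- p$k_off * d_tilde
  out
}

#' Model kinds of nested complexity
#' @return character vector of the three supported stationary models
#' @export
model_kinds <- function() c("poisson_beta", "negative_binomial", "poisson")

.match_kind <- function(kind) {
  match.arg(kind, model_kinds())
}
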