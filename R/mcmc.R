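#' @title Adaptive Metropolis-Hastings machinery
#' @name adaptive_mcmc
#' @description
#' Random-walk Metropolis on log-transformed positive parameters with
#' Haario-style empirical-covariance adaptation and a global scale tuned
#' towards an acceptance rate of 0.234 during burn-in; adaptation is frozen
#' after burn-in so the retained chain is a genuine Markov chain.
NULL

# Core sampler.  logpost takes the natural-scale parameter vector and
# returns the log posterior *excluding* the log-scale Jacobian (added here).
.mh_core <- function(logpost, init, n_iter, burn_in, seed,
                     target_accept = 0.234, thin = 1L) {
  d <- length(init)
  .check(all(init > 0), "initial values must be positive")
  .check(n_iter > burn_in, "n_iter must exceed burn_in")
  set.seed(seed)
  theta <- log(init)
  lp_nat <- logpost(exp(theta))
  tries <- 0L
  while (!is.finite(lp_nat) && tries < 20L) {
    theta <- log(init) + rnorm(d, 0, 0.5)
    lp_nat <- logpost(exp(theta))
    tries <- tries + 1L
  }
  .check(is.finite(lp_nat),
         "could not find a finite initial log-posterior after 20 retries")
  lp <- lp_nat + sum(theta)

  draws <- matrix(NA_real_, n_iter, d)
  lps <- numeric(n_iter)
  # running moments for the empirical covariance
  mu <- theta; S <- diag(1e-4, d)
  cnt <- 1
  log_s <- log(2.38 / sqrt(d))
  chol_prop <- diag(0.1, d)
  n_acc <- 0L
  eps <- diag(1e-9, d)
  for (i in seq_len(n_iter)) {
    step <- exp(log_s) * as.vector(chol_prop %*% rnorm(d))
    prop <- theta + step
    lpn <- logpost(exp(prop))
    lpp <- if (is.finite(lpn)) lpn + sum(prop) else -Inf
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      theta <- prop; lp <- lpp; n_acc <- n_acc + 1L
      acc <- 1
    } else acc <- 0
    draws[i, ] <- exp(theta)
    lps[i] <- lp
    if (i <= burn_in) {
      # running covariance update
      cnt <- cnt + 1
      dlt <- theta - mu
      mu <- mu + dlt / cnt
      S <- S + tcrossprod(dlt, theta - mu)
      log_s <- log_s + (acc - target_accept) / max(10, i)^0.6
      if (i >= max(50, 4 * d) && i %% 25 == 0) {
        cov_emp <- S / (cnt - 1) + eps
        ch <- tryCatch(chol(cov_emp), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- t(ch)
      }
    }
  }
  keep <- seq.int(burn_in + 1L, n_iter, by = thin)
  list(draws = draws, log_post = lps, keep = keep,
       accept_rate = n_acc / n_iter, seed = seed,
       adaptation = list(scale = exp(log_s), chol = chol_prop,
                         frozen_at = burn_in))
}

# sum of log prior densities over the sampled entries
.logprior <- function(par, priors) {
  s <- 0
  for (nm in names(par)) {
    e <- priors[[nm]]
    if (is.null(e)) e <- list(family = "gamma", shape = 1e-3, rate = 1e-3)
    s <- s + .gamma_logprior(par[[nm]], e)
  }
  s
}

.kinetic_names <- function(kind) {
  switch(kind,
    poisson_beta = c("mu_X", "k_on", "k_off"),
    negative_binomial = c("mu_X", "k_on"),
    poisson = "mu_X")
}

# build the (possibly binned) data likelihood for one replicate; returns
# function(kin_named_vector, kappa) -> scalar log-likelihood
.make_replicate_loglik <- function(y, background, n_bins, n_nodes = 96L) {
  if (is.null(background)) {
    # counts observed directly (kappa = 1, no background): tabulate
    yi <- as.integer(round(y))
    tb <- table(yi)
    yu <- as.integer(names(tb)); w <- as.double(tb)
    function(kin, kappa) {
      lp <- .logpmf_table(attr(kin, "kind"), kin, n_nodes)
      xmax <- length(lp) - 1L
      if (any(yu > xmax)) return(-Inf)
      sum(w * lp[yu + 1L])
    }
  } else {
    bn <- .bin_values(y, n_bins)
    a <- background$a; xi <- background$mu_eps; om <- background$sigma_eps
    function(kin, kappa) {
      lp <- .logpmf_table(attr(kin, "kind"), kin, n_nodes)
      ll <- .sn_conv_logdens(bn$y, lp, kappa, a, xi, om)
      if (any(!is.finite(ll))) return(-Inf)
      sum(bn$w * ll)
    }
  }
}

#' Fit a stationary model to flow-FISH data by adaptive Metropolis-Hastings
#'
#' Samples the posterior of the kinetic parameters (and, when a measurement
#' model is present, the replicate scale `kappa`) given per-cell
#' fluorescence.  The latent count is marginalised by truncated summation;
#' the skew-normal background parameters are held at their control-line
#' point estimates (supplied through `priors$eps` or `background`).
#'
#' If `background` is `NULL` and `priors` carries no `eps` entry, the data
#' are interpreted as directly observed counts (`kappa = 1`, no background),
#' which is the mode used for UMI-count fitting.
#'
#' @param data a [flowfish_dataset()], or a bare numeric vector of
#'   fluorescence values / counts; may be empty (`numeric(0)`) to sample the
#'   prior
#' @param kind model kind (see [model_kinds()])
#' @param priors a [default_priors()] object (or compatible named list)
#' @param n_iter total iterations
#' @param burn_in burn-in iterations (default half)
#' @param seed integer seed
#' @param background optional [fit_background()]-style list overriding
#'   `priors$eps`
#' @param fix_kappa optional numeric: hold `kappa` fixed at this value
#'   instead of sampling it
#' @param n_bins histogram bins used to compress the per-cell likelihood
#'   (set `Inf` for exact per-cell evaluation)
#' @param init optional named numeric vector of starting values
#' @param thin thinning interval for retained draws
#' @param pointwise_draws number of retained draws on which per-bin
#'   pointwise log-likelihoods are stored for WAIC
#' @return an object of class `burst_chain`
#' @export
adaptive_mh <- function(data, kind = "negative_binomial",
                        priors = default_priors(kind),
                        n_iter = 4000L, burn_in = floor(n_iter / 2), seed = 1L,
                        background = NULL, fix_kappa = NULL, n_bins = 512L,
                        init = NULL, thin = 1L, pointwise_draws = 200L) {
  kind <- .match_kind(kind)
  y <- if (inherits(data, "flowfish_dataset")) data$fluorescence else
    as.double(data)
  if (is.null(background) && !is.null(priors$eps) &&
      identical(priors$eps$family, "fixed")) {
    background <- priors$eps
  }
  direct_counts <- is.null(background)
  kin_nm <- .kinetic_names(kind)
  sample_kappa <- !direct_counts && is.null(fix_kappa)
  par_nm <- c(kin_nm, if (sample_kappa) "kappa")
  if (direct_counts) fix_kappa <- 1

  no_data <- length(y) == 0L
  llfun <- if (no_data) function(kin, kappa) 0 else
    .make_replicate_loglik(y, background, n_bins)

  logpost <- function(par) {
    names(par) <- par_nm
    kin <- par[kin_nm]
    attr(kin, "kind") <- kind
    kappa <- if (sample_kappa) par[["kappa"]] else fix_kappa
    lp <- .logprior(as.list(par), priors)
    if (!is.finite(lp)) return(-Inf)
    ll <- tryCatch(llfun(kin, kappa), error = function(e) -Inf)
    lp + ll
  }

  if (is.null(init)) {
    init <- .default_init(y, kind, background, priors, sample_kappa)
  }
  init <- init[par_nm]
  res <- .mh_core(logpost, init, n_iter, burn_in, seed, thin = thin)
  colnames(res$draws) <- par_nm

  # pointwise log-likelihood on a thinned subset of retained draws (WAIC)
  pw <- NULL
  if (!no_data && pointwise_draws > 0) {
    idx <- res$keep[unique(round(seq(1, length(res$keep),
                                     length.out = min(pointwise_draws,
                                                      length(res$keep)))))]
    pw <- .pointwise_loglik(y, background, res$draws[idx, , drop = FALSE],
                            kind, kin_nm, sample_kappa, fix_kappa)
  }
  structure(list(draws = res$draws, log_post = res$log_post, keep = res$keep,
                 accept_rate = res$accept_rate, seed = seed, kind = kind,
                 burn_in = burn_in, adaptation = res$adaptation,
                 pointwise = pw, n_cells = length(y)),
            class = "burst_chain")
}

.default_init <- function(y, kind, background, priors, sample_kappa) {
  kap0 <- 1
  if (sample_kappa && !is.null(priors$kappa) &&
      priors$kappa$shape / priors$kappa$rate > 0 &&
      priors$kappa$shape > 1e-2) {
    kap0 <- priors$kappa$shape / priors$kappa$rate
  }
  if (length(y) == 0L) {
    mu0 <- 1
  } else if (is.null(background)) {
    mu0 <- max(mean(y), 0.05)
  } else {
    mu0 <- max((mean(y) - sn_moments(background$a, background$mu_eps,
                                     background$sigma_eps)$mean) / kap0, 0.5)
  }
  ini <- switch(kind,
    poisson_beta = c(mu_X = mu0, k_on = 1, k_off = 1),
    negative_binomial = c(mu_X = mu0, k_on = 1),
    poisson = c(mu_X = mu0))
  if (sample_kappa) ini <- c(ini, kappa = kap0)
  ini
}

.pointwise_loglik <- function(y, background, draws, kind, kin_nm,
                              sample_kappa, fix_kappa, n_bins = 256L) {
  bn <- if (is.null(background)) {
    yi <- as.integer(round(y)); tb <- table(yi)
    list(y = as.integer(names(tb)), w = as.double(tb))
  } else .bin_values(y, n_bins)
  out <- matrix(NA_real_, nrow(draws), length(bn$y))
  for (s in seq_len(nrow(draws))) {
    kin <- draws[s, kin_nm]
    attr(kin, "kind") <- kind
    kappa <- if (sample_kappa) draws[s, "kappa"] else fix_kappa
    lp <- tryCatch(.logpmf_table(kind, kin), error = function(e) NULL)
    if (is.null(lp)) next
    out[s, ] <- if (is.null(background)) {
      xmax <- length(lp) - 1L
      ifelse(bn$y <= xmax, lp[pmin(bn$y, xmax) + 1L], -Inf)
    } else {
      .sn_conv_logdens(bn$y, lp, kappa, background$a, background$mu_eps,
                       background$sigma_eps)
    }
  }
  list(ll = out[complete.cases(out), , drop = FALSE], w = bn$w)
}

#' Highest-posterior-density interval of a sample
#'
#' Shortest contiguous window of the sorted draws containing at least
#' `mass` of them; ties broken towards the leftmost window.
#'
#' @param draws numeric vector (length >= 10)
#' @param mass interval mass in (0, 1), default 0.90
#' @return numeric vector `c(lo, hi)`
#' @export
hpd_interval <- function(draws, mass = 0.90) {
  .check(mass > 0 && mass < 1, "mass must be in (0,1)")
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  .check(n >= 10, "need at least 10 draws")
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k):n] - x[seq_len(n - k + 1L)]
  i <- which.min(widths)          # which.min takes the first (leftmost) tie
  c(x[i], x[i + k - 1L])
}

#' Split-half potential scale reduction factor
#' @param x numeric vector of retained draws
#' @return split-Rhat (1 indicates convergence)
#' @export
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  h <- list(x[seq_len(n)], x[seq.int(length(x) - n + 1L, length(x))])
  m <- vapply(h, mean, 0); v <- vapply(h, var, 0)
  W <- mean(v); B <- n * var(m)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary of a fitted chain
#'
#' Medians and 90% HPD intervals per sampled parameter, plus derived
#' quantities (`CV2_X`, burst size, per-minute rates when `d_tilde` given).
#'
#' @param chain a `burst_chain`
#' @param mass HPD mass (default 0.9)
#' @param d_tilde optional degradation rate (1/min) for unit conversion
#' @return a data frame with columns `parameter`, `median`, `hpd_lo`,
#'   `hpd_hi`, `rhat`
#' @export
posterior_summary <- function(chain, mass = 0.90, d_tilde = NULL) {
  .check(inherits(chain, "burst_chain"), "chain must be a burst_chain")
  dr <- chain$draws[chain$keep, , drop = FALSE]
  derived <- list()
  if (chain$kind == "negative_binomial") {
    derived$burst_size <- dr[, "mu_X"] / dr[, "k_on"]
    derived$CV2_X <- 1 / dr[, "mu_X"] + 1 / dr[, "k_on"]
  } else if (chain$kind == "poisson_beta") {
    s <- dr[, "k_on"] + dr[, "k_off"]
    derived$alpha <- dr[, "mu_X"] * s / dr[, "k_on"]
    derived$burst_size <- derived$alpha / dr[, "k_off"]
    derived$CV2_X <- 1 / dr[, "mu_X"] +
      dr[, "k_off"] / (dr[, "k_on"] * (s + 1))
  } else {
    derived$CV2_X <- 1 / dr[, "mu_X"]
  }
  if (!is.null(d_tilde)) {
    if ("k_on" %in% colnames(dr))
      derived$k_on_tilde <- dr[, "k_on"] * d_tilde
    if ("k_off" %in% colnames(dr))
      derived$k_off_tilde <- dr[, "k_off"] * d_tilde
  }
  cols <- c(as.list(as.data.frame(dr)), derived)
  rows <- lapply(names(cols), function(nm) {
    v <- cols[[nm]]
    h <- hpd_interval(v, mass)
    data.frame(parameter = nm, median = median(v), hpd_lo = h[1],
               hpd_hi = h[2],
               rhat = if (nm %in% colnames(dr)) split_rhat(v) else NA_real_)
  })
  do.call(rbind, rows)
}

#' @export
print.burst_chain <- function(x, ...) {
  cat(sprintf("burst_chain (%s): %d iterations (%d retained), accept %.3f\n",
              x$kind, nrow(x$draws), length(x$keep), x$accept_rate))
  invisible(x)
}

#' Consensus fit across replicates with shared kinetics
#'
#' Joint posterior in which the kinetic parameters are shared across
#' replicates while the scale `kappa` (and the fixed background) are
#' replicate-specific.
#'
#' @param replicates list of [flowfish_dataset()] objects of one condition
#' @param kind model kind
#' @param priors a [default_priors()] object; the `kappa` entry applies to
#'   every replicate
#' @param backgrounds list of per-replicate [fit_background()]-style lists
#'   (recycled if length 1); `NULL` for direct-count data
#' @param n_iter,burn_in,seed,n_bins,thin as in [adaptive_mh()]
#' @return an object of class `burst_chain` with per-replicate `kappa_k`
#'   columns
#' @export
fit_consensus <- function(replicates, kind = "negative_binomial",
                          priors = default_priors(kind), backgrounds = NULL,
                          n_iter = 4000L, burn_in = floor(n_iter / 2),
                          seed = 1L, n_bins = 512L, thin = 1L) {
  kind <- .match_kind(kind)
  .check(is.list(replicates) && length(replicates) >= 1,
         "replicates must be a non-empty list")
  conds <- vapply(replicates, function(r)
    as.character(r$condition %||% "default"), "")
  .check(length(unique(conds)) == 1L,
         "replicates have mismatched conditions: %s",
         paste(unique(conds), collapse = ", "))
  K <- length(replicates)
  if (!is.null(backgrounds) && length(backgrounds) == 1L)
    backgrounds <- rep(backgrounds, K)
  direct <- is.null(backgrounds)
  kin_nm <- .kinetic_names(kind)
  kap_nm <- if (direct) character(0) else paste0("kappa_", seq_len(K))
  par_nm <- c(kin_nm, kap_nm)

  lls <- lapply(seq_len(K), function(k) {
    y <- replicates[[k]]$fluorescence
    .make_replicate_loglik(y, if (direct) NULL else backgrounds[[k]], n_bins)
  })
  logpost <- function(par) {
    names(par) <- par_nm
    kin <- par[kin_nm]
    attr(kin, "kind") <- kind
    pr_list <- as.list(par[kin_nm])
    lp <- .logprior(pr_list, priors)
    for (k in seq_len(K)) {
      if (!direct)
        lp <- lp + .gamma_logprior(par[[kap_nm[k]]],
                                   priors$kappa %||%
                                     list(shape = 1e-3, rate = 1e-3))
      if (!is.finite(lp)) return(-Inf)
      kappa <- if (direct) 1 else par[[kap_nm[k]]]
      ll <- tryCatch(lls[[k]](kin, kappa), error = function(e) -Inf)
      if (!is.finite(ll)) return(-Inf)
      lp <- lp + ll
    }
    lp
  }
  ini_one <- .default_init(replicates[[1]]$fluorescence, kind,
                           if (direct) NULL else backgrounds[[1]],
                           priors, !direct)
  init <- c(ini_one[kin_nm],
            setNames(rep(if (direct) 1 else ini_one[["kappa"]], K), kap_nm))
  res <- .mh_core(logpost, init, n_iter, burn_in, seed, thin = thin)
  colnames(res$draws) <- par_nm
  structure(list(draws = res$draws, log_post = res$log_post, keep = res$keep,
                 accept_rate = res$accept_rate, seed = seed, kind = kind,
                 burn_in = burn_in, adaptation = res$adaptation,
                 pointwise = NULL,
                 n_cells = sum(vapply(replicates, function(r)
                   length(r$fluorescence), 0L))),
            class = "burst_chain")
}

#' Compare fitted models by WAIC
#'
#' Computes the widely applicable information criterion from the stored
#' pointwise log-likelihood of each chain and ranks the models; chains with
#' split-Rhat above 1.1 on any parameter are flagged rather than silently
#' ranked.
#'
#' @param chains named list of `burst_chain` objects fitted to the same data
#' @return a data frame sorted by WAIC (smaller is better) with columns
#'   `model`, `waic`, `se`, `p_waic`, `delta`, `delta_se`, `converged`
#' @export
compare_models <- function(chains) {
  .check(is.list(chains) && length(chains) >= 2, "need at least two chains")
  if (is.null(names(chains)))
    names(chains) <- vapply(chains, function(ch) ch$kind, "")
  stats <- lapply(chains, function(ch) {
    .check(!is.null(ch$pointwise), "chain lacks pointwise log-likelihoods")
    ll <- ch$pointwise$ll; w <- ch$pointwise$w
    lppd_i <- apply(ll, 2L, function(v) {
      m <- max(v); m + log(mean(exp(v - m)))
    })
    p_i <- apply(ll, 2L, var)
    elpd_i <- lppd_i - p_i
    conv <- all(apply(ch$draws[ch$keep, , drop = FALSE], 2L, split_rhat) < 1.1)
    list(elpd_i = elpd_i, w = w, waic = -2 * sum(w * elpd_i),
         p_waic = sum(w * p_i),
         se = 2 * sqrt(sum(w) * sum(w * (elpd_i - sum(w * elpd_i) /
                                           sum(w))^2) / sum(w)),
         converged = conv)
  })
  best <- which.min(vapply(stats, `[[`, 0, "waic"))
  rows <- lapply(names(stats), function(nm) {
    s <- stats[[nm]]; b <- stats[[best]]
    d_i <- s$elpd_i - b$elpd_i
    n <- sum(s$w)
    dse <- 2 * sqrt(n * sum(s$w * (d_i - sum(s$w * d_i) / n)^2) / n)
    data.frame(model = nm, waic = s$waic, se = s$se, p_waic = s$p_waic,
               delta = s$waic - b$waic, delta_se = dse,
               converged = s$converged)
  })
  out <- do.call(rbind, rows)
  out[order(out$waic), ]
}
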