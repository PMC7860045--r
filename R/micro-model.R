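#' Parameters of the microscopic PolII-compartment recycling model
#'
#' PolIIs enter a phase-separated compartment at rate `gamma`, leave it at
#' rate `delta`, and, while the gene is transcribable, initiate transcription
#' at rate `beta` per PolII; upon each transcription event the PolII is
#' re-injected into the compartment with probability `l` (the recycling
#' probability) or lost otherwise.  A TetR repressor at concentration `n`
#' locks the gene at rate `lambda_off = n * K_lambda` (mass action) and the
#' lock releases at `lambda_on = K_lambda`.  mRNA decays at rate `d`.  The
#' `no_accumulation` variant admits influx only when the compartment is
#' empty, so PolIIs cannot pile up ahead of transcription.
#'
#' @param gamma PolII influx rate
#' @param beta per-PolII transcription rate
#' @param delta PolII removal rate
#' @param d mRNA degradation rate
#' @param K_lambda chemical affinity of TetR binding
#' @param n TetR concentration (dimensionless)
#' @param l recycling probability in `[0, 1]`
#' @param variant `"standard"` or `"no_accumulation"`
#' @return an object of class `micro_params`; `lambda_on`/`lambda_off` are
#'   always derived, never stored independently
#' @export
micro_params <- function(gamma = 10, beta = 10, delta = 1, d = 0.01,
                         K_lambda = 0.01, n = 1, l = 0.5,
                         variant = c("standard", "no_accumulation")) {
  variant <- match.arg(variant)
  for (v in c(gamma, beta, delta, d, K_lambda, n))
    .check(is.finite(v) && v >= 0, "all rates must be finite and >= 0")
  .check(l >= 0 && l <= 1, "l must be in [0, 1]")
  structure(list(gamma = gamma, beta = beta, delta = delta, d = d,
                 K_lambda = K_lambda, n = n, l = l, variant = variant),
            class = "micro_params")
}

.micro_packed <- function(p) {
  c(gamma = p$gamma, beta = p$beta, delta = p$delta, d = p$d,
    lambda_on = p$K_lambda, lambda_off = p$n * p$K_lambda, l = p$l,
    variant = if (p$variant == "no_accumulation") 1 else 0)
}

#' Reaction propensities at a microscopic state
#'
#' @param state named list or vector with `polII`, `mRNA` counts and
#'   `dna_on` (0/1)
#' @param p a [micro_params()] object
#' @return named vector of the seven channel rates: `transcribe_reinject`,
#'   `transcribe_lose`, `switch_off`, `switch_on`, `mrna_decay`,
#'   `polII_influx`, `polII_removal`
#' @export
propensities <- function(state, p) {
  .check(inherits(p, "micro_params"), "p must be micro_params")
  P <- state[["polII"]]; M <- state[["mRNA"]]; on <- state[["dna_on"]]
  .check(P >= 0 && M >= 0, "counts must be non-negative")
  tx <- if (on > 0) p$beta * P else 0
  influx <- if (p$variant == "no_accumulation") {
    if (P == 0) p$gamma else 0
  } else p$gamma
  c(transcribe_reinject = p$l * tx,
    transcribe_lose = (1 - p$l) * tx,
    switch_off = if (on > 0) p$n * p$K_lambda else 0,
    switch_on = if (on > 0) 0 else p$K_lambda,
    mrna_decay = p$d * M,
    polII_influx = influx,
    polII_removal = p$delta * P)
}

#' Default initial state: gene on, compartment at its nominal occupancy
#' @param p a [micro_params()] object
#' @return named integer-ish vector `polII`, `mRNA`, `dna_on`
#' @export
micro_init <- function(p) {
  P0 <- if (p$variant == "no_accumulation") 0 else round(p$gamma / p$delta)
  c(polII = as.integer(P0), mRNA = 0L, dna_on = 1L)
}

#' Simulate one exact trajectory of the microscopic model
#'
#' Direct-method stochastic simulation (statistically exact); the event
#' sequence is reproducible given the seed.
#'
#' @param p a [micro_params()] object
#' @param t_end simulation horizon (> 0)
#' @param init initial state (default [micro_init()])
#' @param seed integer seed
#' @param max_events cap on recorded events
#' @return a data frame with columns `time`, `polII`, `mRNA`, `dna_on`
#'   (event-time series including the initial state); if no further event is
#'   possible the trajectory ends early with attribute `stalled = TRUE`
#' @export
simulate_trajectory <- function(p, t_end, init = micro_init(p), seed = 1L,
                                max_events = 5e6) {
  .check(inherits(p, "micro_params"), "p must be micro_params")
  .check(t_end > 0, "t_end must be > 0")
  res <- .micro_ssa_trajectory(.micro_packed(p), t_end,
                               as.integer(init[c("polII", "mRNA", "dna_on")]),
                               as.double(seed), max_events)
  out <- data.frame(time = res$time, polII = res$polII, mRNA = res$mRNA,
                    dna_on = res$dna_on)
  if (isTRUE(res$stalled)) {
    attr(out, "stalled") <- TRUE
    warning("all propensities zero; trajectory ended early")
  }
  if (isTRUE(res$truncated)) {
    attr(out, "truncated") <- TRUE
    warning("event cap reached before t_end")
  }
  out
}

#' Stationary ensemble of mRNA abundances
#'
#' Runs `n_cells` independent realisations to `t_burnin` (sub-seeds derived
#' from the master seed by a counter) and records the terminal state of
#' each.
#'
#' @param p a [micro_params()] object
#' @param n_cells number of independent realisations
#' @param t_burnin burn-in time; a warning is issued below `3/d`
#' @param seed master seed
#' @param init initial state (default [micro_init()])
#' @param n_boot bootstrap resamples for the summary SEs
#' @return list with `mRNA` (integer vector), `polII`, and a `summary` list
#'   (`mean`, `cv2`, `se_mean`, `se_cv2`)
#' @export
stationary_ensemble <- function(p, n_cells, t_burnin = 5 / p$d, seed = 1L,
                                init = micro_init(p), n_boot = 200L) {
  .check(inherits(p, "micro_params"), "p must be micro_params")
  .check(n_cells >= 1, "n_cells must be >= 1")
  if (p$d > 0 && t_burnin < 3 / p$d)
    warning("t_burnin is shorter than 3/d; ensemble may not be stationary")
  m <- .micro_ssa_ensemble(.micro_packed(p), as.integer(n_cells),
                           as.double(t_burnin),
                           as.integer(init[c("polII", "mRNA", "dna_on")]),
                           as.double(seed))
  x <- as.double(m[, "mRNA"])
  set.seed(sub_seed(seed, 7L))
  cv2 <- function(v) if (mean(v) > 0) var(v) / mean(v)^2 else NA_real_
  bs <- if (n_cells > 1) replicate(n_boot, {
    i <- sample.int(n_cells, n_cells, replace = TRUE)
    c(mean(x[i]), cv2(x[i]))
  }) else matrix(NA_real_, 2, 1)
  list(mRNA = m[, "mRNA"], polII = m[, "polII"],
       summary = list(mean = mean(x), cv2 = cv2(x),
                      se_mean = sd(bs[1, ]), se_cv2 = sd(bs[2, ])))
}

# burn-in long enough for the slowest relaxation mode: mRNA decay and the
# DNA on/off equilibration (rate lambda_on + lambda_off)
.relax_time <- function(p) {
  sw <- p$K_lambda * (1 + p$n)
  5 * max(1 / p$d, if (sw > 0) 1 / sw else 0)
}

# stationary first moments of the standard-variant model (the first-moment
# equations are closed because all propensities are linear in the counts):
#   p_on' = lam_on (1 - p_on) - lam_off p_on
#   <P>'  = gamma - delta <P> - (1-l) beta <P 1_on>
#   <P1>' = gamma p_on - (delta + (1-l) beta + lam_off) <P1> + lam_on (<P> - <P1>)
#   <M>'  = beta <P1> - d <M>
.micro_moment_field <- function(s, p) {
  lam_on <- p$K_lambda; lam_off <- p$n * p$K_lambda
  c(p_on = lam_on * (1 - s[1]) - lam_off * s[1],
    P = p$gamma - p$delta * s[2] - (1 - p$l) * p$beta * s[3],
    P1 = p$gamma * s[1] - (p$delta + (1 - p$l) * p$beta + lam_off) * s[3] +
      lam_on * (s[2] - s[3]),
    M = p$beta * s[3] - p$d * s[4])
}

#' Numerically integrated first-moment equations (standard variant)
#'
#' Fourth-order Runge-Kutta integration of the closed first-moment system;
#' used as an independent oracle for the SSA ensemble mean.
#'
#' @param p a [micro_params()] object (standard variant)
#' @param t_end integration horizon
#' @param init initial state as in [simulate_trajectory()]
#' @param dt time step
#' @return named vector of `p_on`, `P` (mean PolII), `P1`, `M` (mean mRNA)
#'   at `t_end`
#' @export
micro_moment_ode <- function(p, t_end, init = micro_init(p), dt = NULL) {
  .check(p$variant == "standard",
         "moment equations are closed only for the standard variant")
  rates <- c(p$K_lambda * (1 + p$n), p$delta + p$beta, p$d)
  if (is.null(dt)) dt <- 0.1 / max(rates, 1e-6)
  s <- c(p_on = as.double(init[["dna_on"]]), P = as.double(init[["polII"]]),
         P1 = as.double(init[["polII"]] * init[["dna_on"]]),
         M = as.double(init[["mRNA"]]))
  t <- 0
  while (t < t_end) {
    h <- min(dt, t_end - t)
    k1 <- .micro_moment_field(s, p)
    k2 <- .micro_moment_field(s + h / 2 * k1, p)
    k3 <- .micro_moment_field(s + h / 2 * k2, p)
    k4 <- .micro_moment_field(s + h * k3, p)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  s
}

#' Exact stationary mean mRNA of the standard-variant model
#'
#' Solves the closed stationary first-moment system.  With `n -> 0` (gene
#' effectively always on) this reduces to
#' `beta * gamma / (d * (delta + (1 - l) * beta))`.
#'
#' @param p a [micro_params()] object (standard variant)
#' @return stationary mean mRNA count
#' @export
stationary_mean_micro <- function(p) {
  .check(p$variant == "standard", "standard variant only")
  lam_on <- p$K_lambda; lam_off <- p$n * p$K_lambda
  p_on <- lam_on / (lam_on + lam_off)
  a <- (1 - p$l) * p$beta
  # 0 = gamma - delta P - a P1 ; 0 = gamma p_on - (delta + a + lam_off) P1
  #                                   + lam_on (P - P1)
  A <- rbind(c(-p$delta, -a),
             c(lam_on, -(p$delta + a + lam_off + lam_on)))
  b <- c(-p$gamma, -p$gamma * p_on)
  sol <- solve(A, b)
  .check(p$d > 0, "d must be > 0")
  p$beta * sol[2] / p$d
}

#' Limiting mean expression as the repressor concentration vanishes
#'
#' Closed form `beta * gamma / (d * (delta + (1 - l) * beta))`, the
#' stationary mean of the always-on linear system.
#'
#' @param p a [micro_params()] object (standard variant)
#' @return limiting mean mRNA count
#' @export
limiting_mean <- function(p) {
  .check(p$variant == "standard", "standard variant only")
  den <- p$d * (p$delta + (1 - p$l) * p$beta)
  .check(den > 0, "zero denominator: d * (delta + (1-l) * beta) must be > 0")
  p$beta * p$gamma / den
}

#' Scan stationary noise over repressor concentration and recycling
#'
#' For each `(n, l)` grid point, simulates a stationary ensemble and records
#' the mean and CV2 with bootstrap SEs; the output feeds noise-versus-mean
#' plots and [odr_noise_fit()].
#'
#' @param p template [micro_params()] object
#' @param n_grid vector of repressor concentrations
#' @param l_grid vector of recycling probabilities
#' @param n_cells ensemble size per grid point
#' @param seed master seed
#' @param t_burnin burn-in time (default: five times the slowest relaxation
#'   timescale, covering both mRNA decay and DNA on/off equilibration)
#' @return data frame `(n, l, mu_X, CV2_X, se_mu, se_cv2)`
#' @export
noise_scan <- function(p, n_grid, l_grid, n_cells = 300L, seed = 1L,
                       t_burnin = NULL) {
  .check(length(n_grid) >= 1 && length(l_grid) >= 1, "grids must be non-empty")
  grid <- expand.grid(n = n_grid, l = l_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pi <- p
    pi$n <- grid$n[i]; pi$l <- grid$l[i]
    en <- stationary_ensemble(pi, n_cells, t_burnin %||% .relax_time(pi),
                              seed = sub_seed(seed, i))
    data.frame(n = pi$n, l = pi$l, mu_X = en$summary$mean,
               CV2_X = en$summary$cv2, se_mu = en$summary$se_mean,
               se_cv2 = en$summary$se_cv2)
  })
  do.call(rbind, rows)
}

#' Scan stationary noise over the mRNA degradation rate
#'
#' @param p template [micro_params()] object (fixed `l`)
#' @param d_grid vector of degradation rates (> 0)
#' @param n_cells ensemble size per grid point
#' @param seed master seed
#' @return data frame `(d, l, mu_X, CV2_X, se_mu, se_cv2)`
#' @export
degradation_scan <- function(p, d_grid, n_cells = 300L, seed = 1L) {
  .check(length(d_grid) >= 1 && all(d_grid > 0), "d_grid must be positive")
  rows <- lapply(seq_along(d_grid), function(i) {
    pi <- p
    pi$d <- d_grid[i]
    en <- stationary_ensemble(pi, n_cells, t_burnin = .relax_time(pi),
                              seed = sub_seed(seed, 100L + i))
    data.frame(d = pi$d, l = pi$l, mu_X = en$summary$mean,
               CV2_X = en$summary$cv2, se_mu = en$summary$se_mean,
               se_cv2 = en$summary$se_cv2)
  })
  do.call(rbind, rows)
}

#' Find the repressor concentration that yields a target stationary mean
#'
#' Uses the exact stationary first-moment solution (no simulation), so two
#' recycling regimes can be compared at matched mean expression.
#'
#' @param p template [micro_params()] object (standard variant)
#' @param target_mu target stationary mean mRNA
#' @param interval search interval for `n`
#' @return the matching `n`
#' @export
match_mean_n <- function(p, target_mu, interval = c(1e-6, 1e4)) {
  f <- function(n) {
    pi <- p; pi$n <- n
    stationary_mean_micro(pi) - target_mu
  }
  .check(f(interval[1]) > 0 && f(interval[2]) < 0,
         "target mean not bracketed by the n interval")
  uniroot(f, interval, tol = 1e-9)$root
}
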