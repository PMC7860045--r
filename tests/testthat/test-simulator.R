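test_that("propensities implement the reaction scheme", {
  p <- micro_params(gamma = 3, beta = 10, delta = 1, d = 0.2, K_lambda = 0.5,
                    n = 4, l = 0.25)
  # DNA off: no transcription, only unbinding / fluxes / decay
  a_off <- propensities(c(polII = 3, mRNA = 2, dna_on = 0), p)
  expect_equal(unname(a_off["transcribe_reinject"]), 0)
  expect_equal(unname(a_off["transcribe_lose"]), 0)
  expect_equal(unname(a_off["switch_on"]), 0.5)
  expect_equal(unname(a_off["switch_off"]), 0)
  # arithmetic: P = 3, l = 0.25, beta = 10 -> 7.5 / 22.5
  a_on <- propensities(c(polII = 3, mRNA = 2, dna_on = 1), p)
  expect_equal(unname(a_on["transcribe_reinject"]), 7.5)
  expect_equal(unname(a_on["transcribe_lose"]), 22.5)
  expect_equal(unname(a_on["switch_off"]), 4 * 0.5)
  expect_equal(unname(a_on["mrna_decay"]), 0.4)
  # no-accumulation variant: influx only into an empty compartment
  pv <- micro_params(gamma = 3, beta = 10, delta = 1, d = 0.2,
                     K_lambda = 0.5, n = 4, l = 0.25,
                     variant = "no_accumulation")
  expect_equal(unname(propensities(c(polII = 2, mRNA = 0, dna_on = 1),
                                   pv)["polII_influx"]), 0)
  expect_equal(unname(propensities(c(polII = 0, mRNA = 0, dna_on = 1),
                                   pv)["polII_influx"]), 3)
  expect_error(propensities(c(polII = -1, mRNA = 0, dna_on = 1), p),
               "non-negative")
})

test_that("SSA reproduces closed-form death and birth-death laws", {
  # pure death: beta = gamma = 0, init mRNA = 10
  p <- micro_params(gamma = 0, beta = 0, delta = 1, d = 0.1, K_lambda = 0.01,
                    n = 1, l = 0)
  en <- suppressWarnings(
    stationary_ensemble(p, 4000, t_burnin = 5,
                        init = c(polII = 0, mRNA = 10, dna_on = 1), seed = 2))
  expect_lt(abs(en$summary$mean - 10 * exp(-0.5)), 4 * en$summary$se_mean)

  # always-on l = 1: PolII is M/M/inf with stationary Poisson(gamma/delta)
  p2 <- micro_params(gamma = 10, beta = 10, delta = 1, d = 0.5,
                     K_lambda = 0.01, n = 0, l = 1)
  en2 <- stationary_ensemble(p2, 4000, t_burnin = 15, seed = 3)
  P <- as.double(en2$polII)
  se_m <- sd(P) / sqrt(length(P))
  expect_lt(abs(mean(P) - 10), 4 * se_m)
  expect_lt(abs(var(P) - 10) / 10, 0.15)
})

test_that("trajectories are seed-reproducible and flag stalls", {
  p <- micro_params(gamma = 2, beta = 5, delta = 1, d = 0.3, K_lambda = 0.2,
                    n = 1, l = 0.5)
  t1 <- simulate_trajectory(p, 20, seed = 7)
  t2 <- simulate_trajectory(p, 20, seed = 7)
  expect_identical(t1, t2)
  t3 <- simulate_trajectory(p, 20, seed = 8)
  expect_false(nrow(t1) == nrow(t3) && all(t1$time == t3$time))
  expect_true(all(diff(t1$time) > 0))
  expect_true(all(t1$mRNA >= 0) && all(t1$polII >= 0))
  # absorbing state: no influx, no DNA switching, nothing left to fire
  p0 <- micro_params(gamma = 0, beta = 0, delta = 1, d = 1, K_lambda = 0,
                     n = 0, l = 0)
  tr <- suppressWarnings(
    simulate_trajectory(p0, 50, init = c(polII = 1, mRNA = 1, dna_on = 1),
                        seed = 1))
  expect_true(isTRUE(attr(tr, "stalled")))
})

test_that("ensemble mean matches the first-moment ODE oracle", {
  set.seed(41)
  for (i in 1:3) {
    p <- micro_params(gamma = runif(1, 2, 8), beta = runif(1, 2, 10),
                      delta = runif(1, 0.5, 2), d = runif(1, 0.1, 0.4),
                      K_lambda = runif(1, 0.05, 0.5), n = runif(1, 0.5, 3),
                      l = runif(1, 0, 1))
    t_end <- 5 / p$d
    mo <- micro_moment_ode(p, t_end)
    en <- stationary_ensemble(p, 2500, t_burnin = t_end, seed = 50 + i)
    expect_lt(abs(en$summary$mean - mo[["M"]]),
              4 * en$summary$se_mean + 0.02 * mo[["M"]])
  }
})

test_that("limiting_mean matches its ODE derivation and the SSA", {
  p <- micro_params(gamma = 10, beta = 10, delta = 1, d = 0.01,
                    K_lambda = 0.01, n = 1e-3, l = 0)
  expect_equal(limiting_mean(p), 10 * 10 / (0.01 * 11), tolerance = 1e-12)
  expect_equal(limiting_mean(p), 909.0909, tolerance = 1e-4)
  p1 <- p; p1$l <- 1
  expect_equal(limiting_mean(p1), 1e4)
  # stationary solution of the full moment system converges to the limit
  expect_equal(stationary_mean_micro(p), limiting_mean(p), tolerance = 2e-3)
  expect_error(limiting_mean(micro_params(1, 1, 0, 0, 1, 1, 1)), "denominator")
})

test_that("no-accumulation variant keeps at most one PolII", {
  pv <- micro_params(gamma = 50, beta = 100, delta = 1, d = 0.05,
                     K_lambda = 0.01, n = 10, l = 0.9,
                     variant = "no_accumulation")
  tr <- simulate_trajectory(pv, 100, seed = 5)
  expect_lte(max(tr$polII), 1)
  en <- stationary_ensemble(pv, 300, t_burnin = 100, seed = 6)
  expect_lte(max(en$polII), 1)
})

test_that("noise_scan and degradation_scan expose the expected trends", {
  p <- micro_params(gamma = 10, beta = 10, delta = 1, d = 0.05,
                    K_lambda = 0.01, n = 1, l = 0.5)
  tab <- noise_scan(p, n_grid = c(0.5, 50), l_grid = 0.5, n_cells = 150L,
                    seed = 3)
  expect_equal(nrow(tab), 2)
  # more repressor -> lower mean (beyond joint SE)
  expect_gt(tab$mu_X[1] - tab$mu_X[2], 3 * sqrt(sum(tab$se_mu^2)))
  dtab <- degradation_scan(p, d_grid = c(0.05, 0.5), n_cells = 150L, seed = 4)
  expect_gt(dtab$mu_X[1], dtab$mu_X[2])
})
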