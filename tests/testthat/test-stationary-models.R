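test_that("poisson_beta_pmf matches closed forms and normalises", {
  p <- kinetic_params(alpha = 1, k_on = 1, k_off = 1)
  # int_0^1 exp(-p) dp = 1 - exp(-1)
  expect_equal(poisson_beta_pmf(0, p), 1 - exp(-1), tolerance = 1e-9)

  for (par in list(c(10, 1, 1), c(50, 0.5, 5), c(5, 3, 0.4), c(200, 2, 8))) {
    kp <- kinetic_params(alpha = par[1], k_on = par[2], k_off = par[3])
    expect_lt(abs(sum(stationary_pmf("poisson_beta", kp)) - 1), 1e-8)
  }
  expect_error(poisson_beta_pmf(-1, p), "non-negative")
  expect_error(poisson_beta_pmf(1.5, p), "non-negative")
})

test_that("poisson_beta_pmf approaches Poisson at large alpha, k rates", {
  # frozen Monte-Carlo oracle check at a nearly-Poisson corner
  p <- kinetic_params(alpha = 50, k_on = 200, k_off = 200)
  pmf <- poisson_beta_pmf(0:120, p)
  poi <- dpois(0:120, 25)
  expect_lt(max(abs(pmf - poi)), 5e-3)
  # and the mixture oracle agrees with the quadrature on a moderate case
  p2 <- kinetic_params(alpha = 20, k_on = 1.5, k_off = 2)
  mc <- mc_pb_pmf(20, 1.5, 2, 40, n = 1e6, seed = 42)
  expect_lt(max(abs(poisson_beta_pmf(0:40, p2) - mc)), 2e-3)
})

test_that("poisson_beta_moments agree with formula and sampling", {
  mo <- poisson_beta_moments(kinetic_params(alpha = 10, k_on = 1, k_off = 1))
  expect_equal(mo$mu_X, 5)
  expect_equal(mo$CV2_X, 0.2 + 1 / 3, tolerance = 1e-12)
  mc <- mc_pb_moments(10, 1, 1, n = 2e5, seed = 7)
  expect_lt(abs(mc$mu - mo$mu_X), 4 * mc$se_mu)
  expect_lt(abs(mc$cv2 - mo$CV2_X) / mo$CV2_X, 0.05)
  # bursting limit: k_off -> Inf at fixed b gives 1/mu + 1/k_on
  b <- 5; k_on <- 2
  cv2_lim <- negbin_moments(k_on, b)$CV2_X
  cv2_big <- poisson_beta_moments(
    kinetic_params(alpha = 1e6 * b, k_on = k_on, k_off = 1e6))$CV2_X
  expect_equal(cv2_big, cv2_lim, tolerance = 1e-3)
})

test_that("negbin_pmf matches the geometric oracle and its limits", {
  # k_on = 1, b = 1: geometric with success prob 1/2
  expect_equal(negbin_pmf(0:5, 1, 1), 0.5^(1:6), tolerance = 1e-12)
  # mean identity
  x <- 0:2000
  expect_equal(sum(x * negbin_pmf(x, 3, 7)), 21, tolerance = 1e-9)
  # Poisson limit
  mu <- 12
  expect_lt(max(abs(negbin_pmf(0:60, 1e4, mu / 1e4) - dpois(0:60, mu))),
            1e-3)
})

test_that("poisson_pmf behaves at the degenerate boundary", {
  expect_equal(poisson_pmf(0, 0), 1)
  expect_equal(poisson_pmf(1, 1), exp(-1))
  expect_error(poisson_pmf(2.5, 1), "non-negative integers")
})

test_that("sample_stationary is reproducible and matches moments", {
  p <- kinetic_params(alpha = 10, k_on = 1, k_off = 1)
  expect_identical(sample_stationary("poisson_beta", p, 100, 3),
                   sample_stationary("poisson_beta", p, 100, 3))
  for (kind in model_kinds()) {
    kp <- switch(kind,
      poisson_beta = kinetic_params(alpha = 30, k_on = 2, k_off = 3),
      negative_binomial = kinetic_params(k_on = 2, burst_size = 6),
      poisson = kinetic_params(mu_X = 9))
    mo <- stationary_moments(kind, kp)
    x <- sample_stationary(kind, kp, 1e5, 11)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mo$mu_X), 4 * se)
    expect_lt(abs(var(x) / mean(x)^2 - mo$CV2_X) / mo$CV2_X, 0.1)
  }
})

test_that("rescale_rates converts to per-minute units and round-trips", {
  p <- kinetic_params(alpha = 4, k_on = 1, k_off = 2)
  r <- rescale_rates(p, d_tilde = 0.5)
  expect_equal(r$k_off_tilde, 1)
  expect_equal(rescale_rates(p, 1)$alpha_tilde, p$alpha)
  expect_equal(r$k_on_tilde / r$d_tilde, p$k_on)
  expect_error(rescale_rates(kinetic_params(alpha = 1, k_on = 1, k_off = 1)),
               "d_tilde")
})

test_that("moment operations agree with sampling for random parameter sets", {
  set.seed(99)
  for (i in 1:20) {
    alpha <- runif(1, 2, 80)
    k_on <- runif(1, 0.2, 5)
    k_off <- runif(1, 0.2, 8)
    kp <- kinetic_params(alpha = alpha, k_on = k_on, k_off = k_off)
    mo <- poisson_beta_moments(kp)
    x <- sample_stationary("poisson_beta", kp, 4e4, seed = 1000 + i)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mo$mu_X), 5 * se)
  }
})
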