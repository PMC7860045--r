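test_that("fit_background recovers skew-normal parameters", {
  set.seed(1)
  y <- rsn(1e4, a = 4, mu_eps = 100, sigma_eps = 20)
  f <- fit_background(y)
  expect_lt(abs(f$a - 4) / 4, 0.10)
  expect_lt(abs(f$mu_eps - 100) / 100, 0.10)
  expect_lt(abs(f$sigma_eps - 20) / 20, 0.10)
  # implied moments reproduce the sample within 5%
  expect_lt(abs(f$mean - mean(y)) / mean(y), 0.05)
  expect_lt(abs(f$sd - sd(y)) / sd(y), 0.05)

  # symmetric truth: skewness estimate near zero
  set.seed(2)
  ys <- rnorm(1e4, 50, 5)
  fs <- fit_background(ys)
  expect_lt(abs(fs$a), 0.6)
  expect_lt(abs(fs$mean - mean(ys)), 0.5)

  expect_error(fit_background(rep(3, 100)), "constant")
})

test_that("calibrate_kappa_prior recovers the scale", {
  d <- data.frame(count = c(5, 10, 20, 50), fluorescence = 2 * c(5, 10, 20, 50))
  cal <- calibrate_kappa_prior(d)
  expect_equal(cal$kappa_hat, 2, tolerance = 1e-6)
  expect_equal(cal$shape / cal$rate, cal$kappa_hat, tolerance = 1e-8)

  set.seed(3)
  cnt <- rep(c(5, 10, 25, 60, 120), each = 8)
  mu <- 3 * cnt
  y <- rgamma(length(cnt), shape = 25, rate = 25 / mu)
  cal2 <- calibrate_kappa_prior(data.frame(count = cnt, fluorescence = y))
  expect_lt(abs(cal2$kappa_hat - 3), 2 * cal2$se * 2)   # within ~2 SE, slack x2

  expect_error(calibrate_kappa_prior(data.frame(count = 1:2,
                                                fluorescence = 1:2)),
               "at least 3")
})

test_that("default_priors are vague gammas with informative overrides", {
  pr <- default_priors("negative_binomial")
  expect_equal(pr$mu_X$shape / pr$mu_X$rate, 1)                  # mean 1
  expect_equal(pr$k_on$shape / pr$k_on$rate^2, 1e3)              # variance 1e3
  cal <- list(shape = 100, rate = 50)
  bg <- list(a = 1, mu_eps = 10, sigma_eps = 2)
  pr2 <- default_priors("negative_binomial", calib = cal, background = bg)
  expect_equal(pr2$kappa$shape, 100)
  expect_equal(pr2$eps$mu_eps, 10)
  expect_identical(pr2$mu_X, pr$mu_X)     # untouched entries stay vague
})

test_that("fluorescence_loglik reduces correctly in limits", {
  meas <- measurement_params(kappa = 2, a = 3, mu_eps = 50, sigma_eps = 8)
  y <- seq(20, 120, by = 5)
  # mu_X -> 0: marginal equals the background density
  kin <- kinetic_params(mu_X = 1e-12, k_on = 1)
  ll <- fluorescence_loglik(y, kin, meas, "negative_binomial")
  expect_equal(ll, dsn(y, 3, 50, 8, log = TRUE), tolerance = 1e-6)
  # a = 0: background is plain normal; single-count check by hand
  meas0 <- measurement_params(kappa = 1, a = 0, mu_eps = 0, sigma_eps = 1)
  kin0 <- kinetic_params(mu_X = 3, k_on = 2)
  ll0 <- fluorescence_loglik(1.3, kin0, meas0, "negative_binomial")
  pmf <- negbin_pmf(0:200, 2, 1.5)
  by_hand <- log(sum(pmf * dnorm(1.3 - 1 * (0:200))))
  expect_equal(ll0, by_hand, tolerance = 1e-8)
})

test_that("fluorescence_loglik matches a Monte-Carlo convolution oracle", {
  meas <- measurement_params(kappa = 2, a = 4, mu_eps = 100, sigma_eps = 20)
  kin <- kinetic_params(k_on = 2, burst_size = 10)
  set.seed(5)
  x <- rnbinom(2e5, size = 2, mu = 20)
  ysim <- rsn(2e5, 4, 100, 20) + 2 * x
  de <- density(ysim, n = 512)
  at <- seq(quantile(ysim, 0.05), quantile(ysim, 0.9), length.out = 25)
  ana <- exp(fluorescence_loglik(at, kin, meas, "negative_binomial"))
  emp <- approx(de$x, de$y, xout = at)$y
  expect_lt(max(abs(ana - emp) / max(ana)), 0.05)
})

test_that("adaptive_mh reproduces the prior when given no data", {
  pr <- default_priors("poisson")
  pr$mu_X <- list(family = "gamma", shape = 3, rate = 0.5)
  ch <- adaptive_mh(numeric(0), kind = "poisson", priors = pr,
                    n_iter = 20000, seed = 3)
  d <- ch$draws[ch$keep, "mu_X"]
  qs <- quantile(d, c(0.1, 0.5, 0.9))
  expect_equal(unname(qs), qgamma(c(0.1, 0.5, 0.9), 3, 0.5),
               tolerance = 0.08)
})

test_that("adaptive_mh matches the conjugate Poisson-gamma posterior", {
  set.seed(9)
  y <- rpois(200, 7)
  pr <- default_priors("poisson")
  pr$mu_X <- list(family = "gamma", shape = 2, rate = 1)
  ch <- adaptive_mh(y, kind = "poisson", priors = pr, n_iter = 8000, seed = 4)
  d <- ch$draws[ch$keep, "mu_X"]
  shape <- 2 + sum(y); rate <- 1 + length(y)
  expect_equal(unname(quantile(d, c(0.1, 0.5, 0.9))),
               qgamma(c(0.1, 0.5, 0.9), shape, rate), tolerance = 0.01)
})

test_that("hpd_interval matches window enumeration and conventions", {
  expect_equal(hpd_interval(1:10, 0.9), c(1, 9))
  expect_equal(hpd_interval(1:10, 0.9), enum_hpd(1:10, 0.9))
  expect_equal(hpd_interval(rep(4, 50)), c(4, 4))
  set.seed(6)
  z <- rnorm(2e5)
  h <- hpd_interval(z, 0.9)
  expect_equal(h[2] - h[1], 2 * qnorm(0.95), tolerance = 0.03)
  set.seed(8)
  for (i in 1:10) {
    dr <- rgamma(200, 2, 1)
    expect_equal(hpd_interval(dr, 0.9), enum_hpd(dr, 0.9))
  }
  expect_error(hpd_interval(1:20, 1.2), "mass")
})

test_that("fit_consensus shares kinetics and is order-invariant", {
  # kappa is calibrated in the intended workflow: without an informative
  # kappa prior the (mu_X, kappa) pair is only weakly identified (they trade
  # off along mean_Y = kappa * mu_X), so the test mirrors the calibrated use
  bg <- list(a = 2, mu_eps = 80, sigma_eps = 15)
  r1 <- quick_flowfish(1200, k_on = 2, b = 12, kappa = 1.8, 2, 80, 15, seed = 21)
  r2 <- quick_flowfish(1200, k_on = 2, b = 12, kappa = 2.4, 2, 80, 15, seed = 22)
  pr <- default_priors("negative_binomial",
                       calib = list(shape = 2^2 / 0.2^2, rate = 2 / 0.2^2))
  cc <- fit_consensus(list(r1, r2), "negative_binomial", pr,
                      backgrounds = list(bg), n_iter = 2500, seed = 2)
  s <- posterior_summary(cc)
  med <- function(nm) s$median[s$parameter == nm]
  expect_lt(abs(med("mu_X") - 24) / 24, 0.15)
  expect_lt(abs(med("k_on") - 2) / 2, 0.15)
  expect_lt(abs(med("kappa_1") - 1.8) / 1.8, 0.15)
  expect_lt(abs(med("kappa_2") - 2.4) / 2.4, 0.15)
  # permuting replicates leaves the shared kinetics unchanged up to MCSE
  cc2 <- fit_consensus(list(r2, r1), "negative_binomial", pr,
                       backgrounds = list(bg), n_iter = 2500, seed = 2)
  s2 <- posterior_summary(cc2)
  expect_lt(abs(med("mu_X") - s2$median[s2$parameter == "mu_X"]) / 24, 0.05)
  # mismatched conditions are rejected
  r3 <- r2; r3$condition <- "other"
  expect_error(fit_consensus(list(r1, r3), "negative_binomial", pr,
                             backgrounds = list(bg)), "mismatched")
})

test_that("compare_models prefers the generating model and ties with itself", {
  set.seed(4)
  y_od <- rnbinom(1200, size = 1, mu = 5)
  chn <- adaptive_mh(y_od, "negative_binomial", n_iter = 2000, seed = 5)
  chp <- adaptive_mh(y_od, "poisson", n_iter = 2000, seed = 6)
  cmp <- compare_models(list(nb = chn, poi = chp))
  expect_equal(cmp$model[1], "nb")
  expect_gt(cmp$delta[cmp$model == "poi"],
            3 * cmp$delta_se[cmp$model == "poi"])
  # Poisson data: Poisson not worse than NB beyond SE
  set.seed(14)
  y_poi <- rpois(1200, 5)
  chn2 <- adaptive_mh(y_poi, "negative_binomial", n_iter = 2000, seed = 7)
  chp2 <- adaptive_mh(y_poi, "poisson", n_iter = 2000, seed = 8)
  cmp2 <- compare_models(list(nb = chn2, poi = chp2))
  poi_row <- cmp2[cmp2$model == "poi", ]
  expect_lt(poi_row$delta, max(3 * poi_row$delta_se, 5))
  # identical chains tie exactly
  cmp3 <- compare_models(list(a = chn, b = chn))
  expect_equal(cmp3$delta, c(0, 0))
})

test_that("partition_by_cycle_size gates phases and sizes as specified", {
  set.seed(31)
  n <- 6000
  phase <- sample(c("G1", "S", "G2"), n, replace = TRUE,
                  prob = c(0.5, 0.2, 0.3))
  dna <- rnorm(n, c(G1 = 1, S = 1.5, G2 = 2)[phase],
               c(G1 = 0.06, S = 0.15, G2 = 0.08)[phase])
  fsc <- rlnorm(n, 0, 0.25)
  d <- flowfish_dataset(rnorm(n, 100, 10), dna_content = dna, fsc_a = fsc)
  part <- partition_by_cycle_size(d)
  expect_true(all(!is.na(part$group)))
  expect_equal(nlevels(part$group), 9)
  # phase recovery is approximate; size quantile fractions are exact-ish
  fr <- prop.table(table(part$size))
  expect_lt(abs(fr[["small"]] - 0.33), 0.02)
  expect_lt(abs(fr[["large"]] - 0.01), 0.005)
  # boundary convention: a cell exactly at a breakpoint goes to the lower group
  dd <- flowfish_dataset(rep(1, 200),
                         dna_content = c(rnorm(100, 1, 0.05),
                                         rnorm(100, 2, 0.05)),
                         fsc_a = rep(1:100, 2))
  pp <- partition_by_cycle_size(dd)
  for (ph in c("G1", "G2")) {
    idx <- pp$phase == ph
    q1 <- quantile(dd$fsc_a[idx], 0.33, names = FALSE)
    at <- idx & dd$fsc_a == q1
    if (any(at)) expect_true(all(pp$size[at] == "small"))
  }
  # unimodal DNA errors
  du <- flowfish_dataset(rep(1, 500), dna_content = rnorm(500, 1, 0.05),
                         fsc_a = runif(500))
  expect_error(partition_by_cycle_size(du), "unimodal|valley")
})

test_that("decompose_noise satisfies the law of total variance exactly", {
  # all means equal -> extrinsic 0
  d0 <- decompose_noise(summary_stats = data.frame(mean = c(2, 2),
                                                   var = c(1, 3),
                                                   weight = c(1, 1)))
  expect_equal(d0$extrinsic, 0)
  # zero within-group variance -> intrinsic 0
  d1 <- decompose_noise(summary_stats = data.frame(mean = c(0, 2),
                                                   var = c(0, 0),
                                                   weight = c(1, 1)))
  expect_equal(d1$intrinsic, 0)
  # two equal groups, means {0, 2}, within-variance 1 -> extrinsic 0.5
  d2 <- decompose_noise(summary_stats = data.frame(mean = c(0, 2),
                                                   var = c(1, 1),
                                                   weight = c(1, 1)))
  expect_equal(d2$extrinsic, 0.5)
  expect_equal(d2$extrinsic + d2$intrinsic, 1)
  expect_equal(unname(hand_decompose(c(0, 2), c(1, 1), c(1, 1))["extrinsic"]),
               d2$extrinsic)
  # cell-level route agrees and fractions stay in [0, 1]
  set.seed(12)
  v <- c(rnorm(300, 0), rnorm(300, 2))
  g <- rep(c("a", "b"), each = 300)
  dc <- decompose_noise(v, g, n_boot = 200)
  expect_true(dc$extrinsic >= 0 && dc$extrinsic <= 1)
  expect_equal(dc$extrinsic + dc$intrinsic, 1)
  expect_error(decompose_noise(v, rep("a", 600)), "at least 2")
})
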