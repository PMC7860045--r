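test_that("generators are deterministic given the master seed", {
  spec <- synth_spec(seed = 5, n_cells = 300, n_sc_genes = 30,
                     n_sc_cells = 200, n_genes = 40)
  expect_identical(synth_flowfish(spec), synth_flowfish(spec))
  expect_identical(synth_control(spec), synth_control(spec))
  expect_identical(synth_calibration(spec), synth_calibration(spec))
  expect_identical(synth_interaction_data(spec), synth_interaction_data(spec))
  expect_identical(synth_umi(spec), synth_umi(spec))
  # a different seed changes the draw
  spec2 <- synth_spec(seed = 6, n_cells = 300)
  expect_false(identical(synth_control(spec)$values,
                         synth_control(spec2)$values))
})

test_that("synth_flowfish respects the measurement equation", {
  # kappa = 1 and vanishing background variance: Y ~ X + mu_eps
  spec <- synth_spec(seed = 7, n_cells = 4000,
                     measurement = measurement_params(kappa = 1, a = 0,
                                                      mu_eps = 0,
                                                      sigma_eps = 1e-6))
  ff <- synth_flowfish(spec)
  y <- ff$replicates[[1]]$fluorescence
  x <- ff$truth$latent[[1]]$X
  expect_lt(max(abs(y - x)), 1e-4)
  # generated CV2 matches the model CV2 within sampling slack
  spec2 <- synth_spec(seed = 8, n_cells = 8000)
  ff2 <- synth_flowfish(spec2)
  x2 <- ff2$truth$latent[[1]]$X
  mo <- negbin_moments(spec2$kinetics$k_on, spec2$kinetics$burst_size)
  expect_lt(abs(var(x2) / mean(x2)^2 - mo$CV2_X) / mo$CV2_X, 0.1)
  # channels present and aligned
  expect_length(ff2$replicates[[1]]$dna_content, 8000)
  expect_length(ff2$replicates[[1]]$fsc_a, 8000)
})

test_that("synth_control matches the skew-normal moment formula", {
  spec <- synth_spec(seed = 9, n_cells = 20000)
  ctrl <- synth_control(spec)
  me <- spec$measurement
  mo <- sn_moments(me$a, me$mu_eps, me$sigma_eps)
  expect_lt(abs(mean(ctrl$values) - mo$mean), 4 * mo$sd / sqrt(20000))
  expect_lt(abs(sd(ctrl$values) - mo$sd) / mo$sd, 0.05)
})

test_that("synth_calibration recovers the scale through the GLM", {
  spec <- synth_spec(seed = 10, calib_cv = 0)
  cal <- calibrate_kappa_prior(synth_calibration(spec))
  expect_equal(cal$kappa_hat, spec$measurement$kappa, tolerance = 1e-6)
  spec2 <- synth_spec(seed = 11, calib_cv = 0.15)
  cal2 <- calibrate_kappa_prior(synth_calibration(spec2))
  expect_lt(abs(cal2$kappa_hat - spec2$measurement$kappa), 4 * cal2$se)
})

test_that("synth_interaction_data plants enrichment only when asked", {
  # enrichment 1: looped and non-looped indistinguishable
  spec0 <- synth_spec(seed = 12, n_genes = 120, enrichment = 1)
  ia0 <- synth_interaction_data(spec0)
  g0 <- filter_genes(ia0$annotation, spec0$bin_size)
  sc0 <- score_genes(ia0$matrix, g0, n_samples = 800, seed = 3)
  j0 <- merge(sc0, ia0$truth, by = "symbol")
  p0 <- wilcox.test(j0$score[j0$looped], j0$score[!j0$looped],
                    alternative = "greater")$p.value
  expect_gt(p0, 0.05)
  # enrichment 10: planted genes rank top
  spec1 <- synth_spec(seed = 12, n_genes = 120, enrichment = 10)
  ia1 <- synth_interaction_data(spec1)
  g1 <- filter_genes(ia1$annotation, spec1$bin_size)
  sc1 <- score_genes(ia1$matrix, g1, n_samples = 800, seed = 3)
  j1 <- merge(sc1, ia1$truth, by = "symbol")
  expect_gt(median(j1$score[j1$looped]), median(j1$score[!j1$looped]))
  # catalogue violations never reach the scores
  expect_false(any(grepl("SYNDUP|SYNSHORT", sc1$symbol)))
})

test_that("synth_umi constructs a recoverable infection experiment", {
  spec <- synth_spec(seed = 13, n_sc_genes = 60, n_sc_cells = 5000)
  um <- synth_umi(spec)
  lab <- infection_split(um$matrix)
  expect_equal(as.character(lab), as.character(um$labels))
  # planted (mu, k_on) recovered within 20% at 5000 cells (well-expressed genes)
  e <- moments_negbin(um$matrix)
  j <- merge(e, um$truth, by = "symbol")
  j <- j[j$mu_uninf > 1 & is.finite(j$k_on), ]
  # compare against the mixture-marginal moments implied by the truth
  w <- spec$infected_fraction
  mu_mix <- (1 - w) * j$mu_uninf + w * j$mu_inf
  expect_lt(median(abs(j$mu_X - mu_mix) / mu_mix), 0.2)
  # zero flu genes -> everyone uninfected
  spec0 <- synth_spec(seed = 14, n_sc_genes = 20, n_sc_cells = 300,
                      n_flu_genes = 0L, infected_fraction = 0)
  um0 <- synth_umi(spec0)
  expect_true(all(um0$labels == "uninfected"))
})
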