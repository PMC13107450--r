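test_that("generators are deterministic given the seed and never touch the
           global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  a <- gen_kinetic_trace(demo_params(), seed = 9)
  b <- gen_kinetic_trace(demo_params(), seed = 9)
  expect_identical(a$intensities, b$intensities)
  expect_identical(.Random.seed, before)

  p1 <- gen_field_profiles("J_BIRADICAL", seed = 9)
  p2 <- gen_field_profiles("J_BIRADICAL", seed = 9)
  expect_identical(lapply(p1, `[[`, "intensities"),
                   lapply(p2, `[[`, "intensities"))
  e1 <- gen_conformer_ensemble(5, seed = 9)
  e2 <- gen_conformer_ensemble(5, seed = 9)
  expect_identical(e1$frames[[5]]$coordinates, e2$frames[[5]]$coordinates)
  d1 <- gen_diffusion_decay(seed = 9)
  d2 <- gen_diffusion_decay(seed = 9)
  expect_identical(d1$intensities, d2$intensities)
  # different seeds give different noise
  expect_false(identical(a$intensities,
                         gen_kinetic_trace(demo_params(), seed = 10)$intensities))
})

test_that("truth records regenerate the noiseless signals exactly", {
  tr <- gen_kinetic_trace(demo_params(), noise_level = 0.05, seed = 2)
  truth <- attr(tr, "truth")
  again <- simulate_observed_kinetics(truth$params, tr$times, truth$pulse)
  expect_equal(truth$noiseless, again$intensities, tolerance = 1e-12)
  # noiseless generation returns the model values themselves
  tr0 <- gen_kinetic_trace(demo_params(), noise_level = 0, seed = 2)
  expect_equal(tr0$intensities, attr(tr0, "truth")$noiseless)

  dec <- gen_diffusion_decay(noise_level = 0, seed = 3)
  expect_equal(dec$intensities, attr(dec, "truth")$noiseless)

  prof <- gen_field_profiles("J_BIRADICAL", snr = 0, seed = 4,
                             peak_field = 1e-2)
  truth <- attr(prof, "truth")
  expect_equal(prof[[1]]$intensities, truth$clean[[1]])
})

test_that("kinetic designs match the two experimental protocols", {
  trA <- gen_kinetic_trace(demo_params(), seed = 1)
  expect_equal(trA$times, c(0, 3, 100) * 1e-6)
  expect_equal(attr(trA, "truth")$pulse$effective_offset, 2e-6)
  trB <- gen_kinetic_trace(demo_params(),
                           delays = seq(0, 100e-6, length.out = 10),
                           pulse = pulse_timing(2e-6), seed = 1)
  expect_length(trB$times, 10)
  expect_equal(range(trB$times), c(0, 100e-6))
})

test_that("field grid spans 1 mT to 9.4 T with 30 log-spaced points", {
  prof <- gen_field_profiles("NONE", seed = 1)
  f <- prof[[1]]$fields
  expect_length(f, 30)
  expect_equal(f[1], 1e-3, tolerance = 1e-12)
  expect_equal(f[30], 9.4, tolerance = 1e-12)
  expect_equal(diff(log10(f)), rep(diff(log10(c(1e-3, 9.4))) / 29, 29),
               tolerance = 1e-12)
  expect_error(gen_field_profiles("J_BIRADICAL", peak_field = 20, seed = 1),
               "outside")
})

test_that("conformer generator realises the requested fractions and labels", {
  ens <- gen_conformer_ensemble(300, stacked_fraction = 0.2,
                                hbond_fraction = 0.05, seed = 12)
  st <- ensemble_statistics(ens)
  # construction is exact per frame, so the recovered fractions equal the
  # Bernoulli draws, which match the truth within binomial error
  p_hat <- mean(st$per_frame$stacked)
  expect_lt(abs(p_hat - 0.2), 3 * sqrt(0.2 * 0.8 / 300))
  expect_identical(st$per_frame$label, ens$truth$label)
  # all-cis compact labels with large drawn distances put the distance mode
  # beyond 10 angstrom
  ccc <- gen_conformer_ensemble(200, stacked_fraction = 0,
                                hbond_fraction = 0,
                                label_probs = c(CCC = 1), seed = 13)
  stc <- ensemble_statistics(ccc)
  expect_true(all(stc$per_frame$label == "CCC"))
  dens <- stc$densities$distance$by_label$Sum
  expect_gt(dens$mids[which.max(dens$density)], 10)
  expect_error(gen_conformer_ensemble(10, stacked_fraction = 0.7,
                                      hbond_fraction = 0.5), "<= 1")
  expect_error(gen_conformer_ensemble(10, label_probs = c(TTX = 1)), "label_probs")
})

test_that("generator-classifier closed loop labels correctly at moderate n", {
  for (mech in c("J_BIRADICAL", "DG_INTERMOLECULAR", "LOWFIELD_HFC", "NONE")) {
    for (s in 1:5) {
      prof <- gen_field_profiles(mech, snr = 10, seed = 100 + s)
      call <- classify_mechanism(prof)
      expect_equal(call$label, mech,
                   info = sprintf("mechanism %s seed %d", mech, 100 + s))
    }
  }
  # J peak field is located to within one grid step
  prof <- gen_field_profiles("J_BIRADICAL", peak_field = 13e-3, snr = 20,
                             seed = 7)
  call <- classify_mechanism(prof)
  step <- diff(log10(c(1e-3, 9.4))) / 29
  expect_lt(abs(log10(call$peak_field) - log10(13e-3)), step + 1e-9)
})

test_that("diffusion design defaults follow the experimental protocol", {
  dec <- gen_diffusion_decay(seed = 1)
  expect_length(dec$gradients, 16)
  # 2-95% of 50 G/cm = 0.5 T/m, linear increments
  expect_equal(dec$gradients[1], 0.02 * 0.5, tolerance = 1e-12)
  expect_equal(dec$gradients[16], 0.95 * 0.5, tolerance = 1e-12)
  expect_equal(diff(dec$gradients), rep(diff(dec$gradients)[1], 15),
               tolerance = 1e-12)
  expect_equal(dec$big_delta, 50e-3)
  expect_equal(dec$little_delta, 2e-3)
  # round trip through the fitter
  fit <- stejskal_tanner_fit(dec)
  expect_lt(abs(fit$D / attr(dec, "truth")$D - 1), 0.02)
})
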