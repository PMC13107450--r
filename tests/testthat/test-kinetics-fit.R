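test_that("noiseless dense round-trip recovers all free parameters to 0.1%", {
  pulse <- default_pulse()
  truth <- kinetic_parameters(kt_R0 = 2.3e5, T1 = 140e-6, scale = 1.7)
  tr <- simulate_observed_kinetics(truth, seq(0, 100e-6, length.out = 12),
                                   pulse)
  fit <- fit_kinetics(tr, pulse, kinetic_fit_spec(seed = 7))
  est <- fit$params[[1]]
  expect_lt(abs(est$kt_R0 / truth$kt_R0 - 1), 1e-3)
  expect_lt(abs(est$T1 / truth$T1 - 1), 1e-3)
  expect_lt(abs(est$scale / truth$scale - 1), 1e-3)
  expect_lt(fit$residual_norm, 1e-12)
  expect_true(fit$converged)
})

test_that("freeing only the scale solves the linear sub-problem exactly", {
  pulse <- default_pulse()
  truth <- kinetic_parameters(kt_R0 = 1e5, T1 = 120e-6, scale = 2.5)
  tr <- simulate_observed_kinetics(truth, c(0, 3e-6, 100e-6), pulse)
  sp <- kinetic_fit_spec(free = "scale",
                         fixed = list(kt_R0 = 1e5, T1 = 120e-6))
  fit <- fit_kinetics(tr, pulse, sp)
  expect_equal(fit$params[[1]]$scale, 2.5, tolerance = 1e-10)
  expect_lt(fit$residual_norm, 1e-20)
})

test_that("shared-parameter joint fit recovers a common kt_R0", {
  pulse <- default_pulse()
  k <- 1.5e5
  tw <- simulate_observed_kinetics(kinetic_parameters(k, 300e-6, scale = 2),
                                   seq(0, 100e-6, length.out = 8), pulse,
                                   proton_label = "W6")
  tf <- simulate_observed_kinetics(kinetic_parameters(k, 60e-6, scale = 0.7),
                                   seq(0, 100e-6, length.out = 8), pulse,
                                   proton_label = "F8'")
  fit <- fit_kinetics(list(tw, tf), pulse,
                      kinetic_fit_spec(shared = "kt_R0", seed = 3))
  expect_equal(fit$params[[1]]$kt_R0, fit$params[[2]]$kt_R0)
  expect_lt(abs(fit$params[[1]]$kt_R0 / k - 1), 1e-3)
  expect_lt(abs(fit$params[[1]]$T1 / 300e-6 - 1), 1e-3)
  expect_lt(abs(fit$params[[2]]$T1 / 60e-6 - 1), 1e-3)
  expect_equal(sum(fit$estimates$parameter == "kt_R0"), 1)
})

test_that("fit result is invariant under time-unit conversion at input", {
  # the disk format stores microseconds; reading converts to seconds, and a
  # fit of the converted trace equals a fit of the native-seconds trace
  pulse <- default_pulse()
  truth <- kinetic_parameters(kt_R0 = 1e5, T1 = 90e-6, scale = 1.2)
  tr <- gen_kinetic_trace(truth, delays = seq(0, 100e-6, length.out = 8),
                          noise_level = 0.03, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  f1 <- fit_kinetics(tr, pulse, kinetic_fit_spec(seed = 5))
  f2 <- fit_kinetics(tr2, pulse, kinetic_fit_spec(seed = 5))
  expect_equal(f1$params[[1]]$T1, f2$params[[1]]$T1, tolerance = 1e-6)
  expect_equal(f1$params[[1]]$kt_R0, f2$params[[1]]$kt_R0, tolerance = 1e-6)
})

test_that("degenerate and under-determined inputs raise informative errors", {
  pulse <- default_pulse()
  zero <- kinetic_trace("z", c(0, 1e-6, 2e-6), c(0, 0, 0))
  expect_error(fit_kinetics(zero, pulse), "degenerate")
  # a 3-point trace exactly supports the 3 free parameters
  short <- kinetic_trace("s", c(0, 1e-6, 2e-6), c(1, 2, 1))
  expect_s3_class(fit_kinetics(short, pulse,
                               kinetic_fit_spec(n_starts = 2)),
                  "kinetic_fit")
  expect_error(kinetic_fit_spec(free = "gamma"), "subset")
  expect_error(kinetic_fit_spec(shared = "T1", free = c("kt_R0", "scale")),
               "shared")
  expect_error(kinetic_fit_spec(bounds = list(T1 = c(-1, 1))), "positive")
})

test_that("identifiability profile is flat for T1 far beyond the window and
           parabolic for kt_R0 on dense data", {
  pulse <- default_pulse()
  # noisy 3-delay trace generated with T1 >> max delay: T1 profile is flat
  truth <- kinetic_parameters(kt_R0 = 1e5, T1 = 5e-3)
  tr3 <- gen_kinetic_trace(truth, noise_level = 0.05, seed = 17)
  sp <- kinetic_fit_spec(seed = 2, n_starts = 4)
  grid <- 5e-3 * c(1, 2, 5, 10)
  prof <- profile_identifiability(tr3, pulse, sp, "T1", grid)
  expect_equal(nrow(prof), length(grid))
  expect_lt(max(prof$residual_norm) / min(prof$residual_norm), 2)
  # dense noiseless trace: kt_R0 profile has its minimum at the truth
  tr <- simulate_observed_kinetics(kinetic_parameters(1e5, 1.2e-4),
                                   seq(0, 100e-6, length.out = 10), pulse)
  kgrid <- 1e5 * c(0.5, 0.8, 1, 1.25, 2)
  prof2 <- profile_identifiability(tr, pulse, sp, "kt_R0", kgrid)
  expect_equal(which.min(prof2$residual_norm), 3)
  expect_true(all(diff(prof2$residual_norm[3:5]) > 0))
  expect_true(all(diff(prof2$residual_norm[1:3]) < 0))
  # empty grid -> empty table
  empty <- profile_identifiability(tr, pulse, sp, "T1", numeric(0))
  expect_equal(nrow(empty), 0)
})

test_that("median recovery at the sparse design stays within 15% (one row)", {
  # one dyad-style global fit repeated over noisy replicates, on the row
  # whose relaxation times both sit inside the kinetic window (so the
  # estimator spread is small at this replicate count); the full table
  # sweep lives in the acceptance suite
  med <- dyad_recovery_medians(T1_w = 29e-6, T1_f = 19e-6, kt_R0 = 4.2e5,
                               n_replicates = 50, seed_base = 100)
  expect_lt(abs(med["T1_w"] / 29e-6 - 1), 0.15)
  expect_lt(abs(med["T1_f"] / 19e-6 - 1), 0.15)
  expect_lt(abs(med["kt_R0"] / 4.2e5 - 1), 0.15)
})
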