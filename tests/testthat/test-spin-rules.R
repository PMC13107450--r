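test_that("high-field sign rule equals the brute-force four-factor product", {
  grid <- expand.grid(dg = c(-1, 1), a = c(-1, 1), mu = c(-1, 1),
                      eps = c(-1, 1))
  got <- apply(grid, 1, function(r) {
    kaptein_high_field_sign(radical_pair_config(r["dg"], r["a"], r["mu"],
                                                r["eps"]))
  })
  expect_equal(got, grid$dg * grid$a * grid$mu * grid$eps)
  # single sign flip flips the result
  expect_equal(kaptein_high_field_sign(radical_pair_config(1, 1, 1, 1)), 1)
  expect_equal(kaptein_high_field_sign(radical_pair_config(1, 1, -1, 1)), -1)
})

test_that("J-resonance sign rule equals the three-factor product and is
           nucleus-independent", {
  grid <- expand.grid(J = c(-1, 1), mu = c(-1, 1), eps = c(-1, 1))
  got <- apply(grid, 1, function(r) {
    j_resonance_sign(radical_pair_config(1, 1, r["mu"], r["eps"],
                                         sgn_J = r["J"]))
  })
  expect_equal(got, grid$J * grid$mu * grid$eps)
  # triplet-precursor geminate biradical with negative J: emissive
  expect_equal(j_resonance_sign(radical_pair_config(1, 1, 1, 1, sgn_J = -1)),
               -1)
  # independent of the hyperfine sign
  expect_equal(j_resonance_sign(radical_pair_config(1, -1, 1, 1, sgn_J = -1)),
               j_resonance_sign(radical_pair_config(1, 1, 1, 1, sgn_J = -1)))
  expect_error(j_resonance_sign(radical_pair_config(1, 1, 1, 1, sgn_J = 0)),
               "not applicable")
})

test_that("LAC field maps |J|/h = 280.2 MHz near 10 mT and inverts exactly", {
  expect_equal(lac_field(0), 0)
  B <- lac_field(280.2e6, unit = "Hz", g = 2.0023)
  expect_equal(B, 0.0100, tolerance = 1e-3)
  # exact inverse composition in both unit systems
  for (B0 in c(1e-3, 0.01, 0.35, 9.4)) {
    expect_equal(lac_field(j_from_field(B0, "J"), "J"), B0,
                 tolerance = 1e-12)
    expect_equal(lac_field(j_from_field(B0, "Hz"), "Hz"), B0,
                 tolerance = 1e-12)
  }
  expect_equal(lac_field(j_from_field(0.01, "J")), 0.01, tolerance = 1e-12)
  expect_error(lac_field(-1), ">= 0")
})

test_that("field-regime banding reproduces the documented cases", {
  expect_equal(classify_field_regime(1e-3, a_scale = 1e-3, J_field = 1e-2),
               "LOW_HFC")
  expect_equal(classify_field_regime(1e-2, a_scale = 1e-4, J_field = 1e-2),
               "INTERMEDIATE_J")
  expect_equal(classify_field_regime(9.4, a_scale = 1e-4, J_field = 1e-2),
               "HIGH_DG")
  # the 0.1-1 T null window maps to GAP
  expect_equal(classify_field_regime(0.3, a_scale = 1e-3, J_field = 1e-2),
               "GAP")
})

test_that("profile normalization rescales to the 10 mT feature and is
           idempotent", {
  fields <- cidnpdyad:::default_field_grid()
  shape <- -4 * exp(-(log10(fields) - log10(0.01))^2 / 0.08)
  p <- field_profile("F8'", fields, shape)
  n1 <- normalize_profiles(p, reference_field = 0.01)[[1]]
  ref <- approx(log10(n1$fields), n1$intensities, xout = log10(0.01))$y
  expect_equal(abs(ref), 1, tolerance = 1e-12)
  expect_lt(max(n1$intensities), 0) # sign preserved
  # two profiles differing by a global factor collapse onto each other
  q <- field_profile("W6", fields, 3.7 * shape)
  nq <- normalize_profiles(q, reference_field = 0.01)[[1]]
  expect_equal(n1$intensities, nq$intensities, tolerance = 1e-12)
  # idempotence
  n2 <- normalize_profiles(n1, reference_field = 0.01)[[1]]
  expect_equal(n2$intensities, n1$intensities, tolerance = 1e-12)
  # log-interpolated reference between grid points matches the closed form
  p2 <- field_profile("x", c(8e-3, 12.5e-3, 2e-2), c(2, 4, 8))
  n3 <- normalize_profiles(p2, reference_field = 0.01)[[1]]
  lam <- (log10(0.01) - log10(8e-3)) / (log10(12.5e-3) - log10(8e-3))
  expect_equal(n3$intensities[1], 2 / (2 + lam * 2), tolerance = 1e-12)
  # degenerate reference
  z <- field_profile("z", c(5e-3, 1e-2, 2e-2), c(-1, 0, 1))
  expect_error(normalize_profiles(z, reference_field = 0.01), "degenerate")
})

test_that("mechanism classifier identifies the canonical synthetic cases", {
  jb <- gen_field_profiles("J_BIRADICAL", peak_field = 13e-3, snr = 10,
                           seed = 42)
  call <- classify_mechanism(jb)
  expect_equal(call$label, "J_BIRADICAL")
  expect_lt(abs(log10(call$peak_field) - log10(13e-3)), 0.15)
  expect_equal(call$sign_uniformity, 1)
  expect_gte(call$highfield_ratio, 3)

  dg <- gen_field_profiles("DG_INTERMOLECULAR", snr = 10, seed = 43)
  expect_equal(classify_mechanism(dg)$label, "DG_INTERMOLECULAR")

  lf <- gen_field_profiles("LOWFIELD_HFC", snr = 10, seed = 44)
  expect_equal(classify_mechanism(lf)$label, "LOWFIELD_HFC")

  none <- gen_field_profiles("NONE", snr = 10, seed = 45)
  expect_equal(classify_mechanism(none)$label, "NONE")

  # flat zero profiles (noiseless) are NONE, single profile is an error
  fields <- cidnpdyad:::default_field_grid()
  flat <- list(field_profile("a", fields, rep(0, 30)),
               field_profile("b", fields, rep(0, 30)))
  expect_equal(classify_mechanism(flat)$label, "NONE")
  expect_error(classify_mechanism(flat[1]), "insufficient")
})

test_that("field profile validation enforces the grid invariants", {
  expect_error(field_profile("x", c(2, 1, 3), c(1, 1, 1)), "increasing")
  expect_error(field_profile("x", c(0, 1, 2), c(1, 1, 1)), "> 0")
  expect_error(field_profile("x", c(1, 2), c(1, 1, 1)), "match")
})
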