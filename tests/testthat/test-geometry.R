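# Small hand-built frame: four atoms defining a dihedral plus two rings.
quad_frame <- function(p4, extra = NULL) {
  base <- rbind(c(1.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0), p4)
  ring <- polygon_frame()
  n0 <- nrow(base)
  labeled_frame(
    atom_names = c(paste0("Q", 1:4), ring$atom_names),
    coordinates = rbind(base, ring$coordinates),
    f_mask = n0 + ring$f_mask, w_mask = n0 + ring$w_mask,
    omega_quads = list(c(1L, 2L, 3L, 4L)))
}

test_that("omega dihedral reproduces canonical arrangements and chirality", {
  # anti-periplanar: fourth atom on the opposite side
  fr <- quad_frame(c(3.0, -1, 0))
  expect_equal(abs(omega_dihedral(fr, 1)), 180, tolerance = 1e-9)
  # syn-periplanar
  fr0 <- quad_frame(c(3.0, 1, 0))
  expect_equal(omega_dihedral(fr0, 1), 0, tolerance = 1e-9)
  # out-of-plane, against an independent implementation (bio3d)
  fr1 <- quad_frame(c(2.0, 0.8, 1.1))
  ref <- bio3d::torsion.xyz(as.numeric(t(fr1$coordinates[1:4, ])))
  expect_equal(omega_dihedral(fr1, 1), as.numeric(ref), tolerance = 1e-6)
  # mirror image flips the sign
  fr2 <- fr1
  fr2$coordinates[, 3] <- -fr2$coordinates[, 3]
  expect_equal(omega_dihedral(fr2, 1), -omega_dihedral(fr1, 1),
               tolerance = 1e-9)
  expect_error(omega_dihedral(fr1, 5), "no omega quad")
  # collinear defining atoms are degenerate
  degen <- quad_frame(c(3.0, 0, 0))
  degen$coordinates[1, ] <- c(-1, 0, 0)
  expect_error(omega_dihedral(degen, 1), "collinear")
})

test_that("cis/trans classification applies the 90 degree cut, boundary to
           trans", {
  expect_equal(classify_cis_trans(c(0, 10, 170, -175, 89.9, 90, -90)),
               c("C", "C", "T", "T", "C", "T", "T"))
  # per-residue labelling, flavin-first
  fr <- quad_frame(c(2.0, 0.8, 1.1))
  om <- omega_dihedral(fr, 1)
  expect_equal(label_frame(fr), classify_cis_trans(om))
})

test_that("moiety centers and inter-plane angles match closed-form cases", {
  fr <- polygon_frame(dz = 5)
  expect_equal(moiety_center_distance(fr), 5, tolerance = 1e-12)
  # coplanar rings: parallel (0 or 180)
  th <- interplane_angle(fr)
  expect_true(min(th, 180 - th) < 1e-9)
  # perpendicular rings
  fr2 <- fr
  ring2 <- fr$coordinates[fr$w_mask, ]
  ring2 <- ring2 %*% t(matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE))
  fr2$coordinates[fr2$w_mask, ] <- ring2
  expect_equal(interplane_angle(fr2), 90, tolerance = 1e-9)
  # random frame centroid distance equals the brute-force computation
  set.seed(31)
  co <- matrix(rnorm(36), ncol = 3)
  fr3 <- labeled_frame(paste0("A", 1:12), co, f_mask = 1:5, w_mask = 6:12)
  brute <- sqrt(sum((colMeans(co[1:5, ]) - colMeans(co[6:12, ]))^2))
  expect_equal(moiety_center_distance(fr3), brute, tolerance = 1e-12)
  # collinear mask has no plane
  line <- cbind(1:6, 0, 0)
  fr4 <- labeled_frame(paste0("A", 1:12), rbind(line, co[1:6, ]),
                       f_mask = 1:6, w_mask = 7:12)
  expect_error(interplane_angle(fr4), "collinear")
})

test_that("noisy planar hexagon recovers the analytic normal within 1 degree", {
  set.seed(77)
  worst <- 0
  for (i in 1:25) {
    fr <- polygon_frame(noise = 0.01)
    th <- interplane_angle(fr)
    worst <- max(worst, min(th, 180 - th))
  }
  expect_lt(worst, 1)
})

test_that("stacking band and hydrogen-bond rules follow the stated criteria", {
  expect_true(is_stacked(5.0, 10))
  expect_true(is_stacked(5.0, 170))
  expect_false(is_stacked(7.0, 10))
  expect_false(is_stacked(5.0, 90))
  # distance endpoints inclusive, angle bounds strict
  expect_true(is_stacked(3.0, 10) && is_stacked(6.5, 10))
  expect_false(is_stacked(5.0, 45) || is_stacked(5.0, 135))
  expect_true(is_stacked(5.0, 44.999) && is_stacked(5.0, 135.001))

  # ideal near-linear N-H...O=C geometry
  mk <- function(HO, nho_bend = 0) {
    # N -- H ... O -- C along x, with optional bend at H
    N <- c(0, 0, 0)
    H <- c(1.0, 0, 0)
    O <- H + HO * c(cos(nho_bend * pi / 180), sin(nho_bend * pi / 180), 0)
    C <- O + c(1.2, 0.1, 0)
    ring <- polygon_frame()
    labeled_frame(c("N", "H", "O", "C", ring$atom_names),
                  rbind(N, H, O, C, ring$coordinates + 20),
                  f_mask = 4 + ring$f_mask, w_mask = 4 + ring$w_mask,
                  donor_quads = matrix(1:4, 1))
  }
  expect_true(is_hbond(mk(1.9)))
  expect_false(is_hbond(mk(3.5)))
  expect_false(is_hbond(mk(2.0, nho_bend = 80))) # N-H...O angle 100 degrees
  expect_false(is_hbond(polygon_frame()))        # no donor declared
})

test_that("classification of 1000 generated frames equals a brute-force loop", {
  ens <- gen_conformer_ensemble(1000, stacked_fraction = 0.25,
                                hbond_fraction = 0.1, seed = 5)
  st <- ensemble_statistics(ens)
  crit <- geometry_criteria()
  brute <- vapply(ens$frames, function(fr) {
    x <- fr$coordinates
    cf <- colMeans(x[fr$f_mask, , drop = FALSE])
    cw <- colMeans(x[fr$w_mask, , drop = FALSE])
    d <- sqrt(sum((cf - cw)^2))
    nrm <- function(idx) {
      m <- sweep(x[idx, , drop = FALSE], 2,
                 colMeans(x[idx, , drop = FALSE]))
      svd(m)$v[, 3]
    }
    th <- acos(min(1, max(-1, sum(nrm(fr$f_mask) * nrm(fr$w_mask))))) * 180 / pi
    stacked <- d >= 3 && d <= 6.5 && (th < 45 || th > 135)
    hb <- FALSE
    for (r in seq_len(nrow(fr$donor_quads))) {
      q <- fr$donor_quads[r, ]
      dho <- sqrt(sum((x[q[2], ] - x[q[3], ])^2))
      a1 <- cidnpdyad:::vertex_angle(x[q[1], ], x[q[2], ], x[q[3], ])
      a2 <- cidnpdyad:::vertex_angle(x[q[2], ], x[q[3], ], x[q[4], ])
      if (dho < 3 && a1 > 130 && a2 > 130) hb <- TRUE
    }
    oms <- vapply(seq_along(fr$omega_quads), function(k) {
      q <- fr$omega_quads[[k]]
      cidnpdyad:::dihedral_angle(x[q[1], ], x[q[2], ], x[q[3], ], x[q[4], ])
    }, 1.0)
    lab <- paste(ifelse(abs(oms) < 90, "C", "T"), collapse = "")
    c(stacked = stacked, hbond = hb, label = lab)
  }, c(stacked = "", hbond = "", label = ""))
  expect_identical(st$per_frame$stacked, as.logical(brute["stacked", ]))
  expect_identical(st$per_frame$hbond, as.logical(brute["hbond", ]))
  expect_identical(st$per_frame$label, unname(brute["label", ]))
  # and the generator's intent is realised exactly
  expect_identical(st$per_frame$stacked, ens$truth$class == "stacked")
  expect_identical(st$per_frame$hbond, ens$truth$class == "hbond")
  expect_identical(st$per_frame$label, ens$truth$label)
})

test_that("geometric operators are invariant under rigid motions", {
  set.seed(99)
  ens <- gen_conformer_ensemble(20, stacked_fraction = 0.3,
                                hbond_fraction = 0.2, seed = 8)
  for (fr in ens$frames[1:10]) {
    R <- random_rotation_matrix()
    shift <- rnorm(3, 0, 20)
    fr2 <- apply_rigid(fr, R, shift)
    expect_equal(moiety_center_distance(fr2), moiety_center_distance(fr),
                 tolerance = 1e-9)
    th1 <- interplane_angle(fr)
    th2 <- interplane_angle(fr2)
    expect_lt(min(abs(th2 - th1), abs(180 - th1 - th2)), 1e-6)
    expect_equal(omega_dihedral(fr2, 1), omega_dihedral(fr, 1),
                 tolerance = 1e-6)
    expect_identical(is_hbond(fr2), is_hbond(fr))
  }
})

test_that("ensemble statistics: conditional probabilities, mixture linearity
           and degenerate inputs", {
  ens <- gen_conformer_ensemble(400, stacked_fraction = 1, hbond_fraction = 0,
                                seed = 3)
  st <- ensemble_statistics(ens)
  expect_true(all(st$by_label$p_stacked == 1))
  expect_error(ensemble_statistics(list()), "empty")

  ens2 <- gen_conformer_ensemble(600, stacked_fraction = 0.3,
                                 hbond_fraction = 0.1, seed = 9)
  st2 <- ensemble_statistics(ens2)
  # densities integrate to 1 per label
  for (l in names(st2$densities$distance$by_label)) {
    h <- st2$densities$distance$by_label[[l]]
    bw <- diff(st2$densities$distance$breaks)
    if (sum(h$counts) > 0) expect_equal(sum(h$density * bw), 1, tolerance = 1e-9)
  }
  # pooled density equals the label-population-weighted mixture
  labs <- st2$by_label$label
  w <- st2$by_label$weight
  mix <- Reduce(`+`, lapply(seq_along(labs), function(i) {
    w[i] * st2$densities$distance$by_label[[labs[i]]]$density
  }))
  expect_equal(st2$densities$distance$by_label$Sum$density, mix,
               tolerance = 1e-12)
  # per-frame counting equals the reported conditional probabilities
  pf <- st2$per_frame
  for (i in seq_len(nrow(st2$by_label))) {
    l <- st2$by_label$label[i]
    expect_equal(st2$by_label$p_stacked[i], mean(pf$stacked[pf$label == l]))
  }
})

test_that("per-atom energy difference normalises as stated", {
  expect_equal(per_atom_energy_difference(26, 0, 108), 26 / 108)
  expect_lt(abs(per_atom_energy_difference(26, 0, 108) - 0.25), 0.01)
  expect_equal(per_atom_energy_difference(5, 5, 20), 0)
  expect_equal(per_atom_energy_difference(10, 0, 10), 1)
  expect_error(per_atom_energy_difference(1, 0, 0), "n_atoms")
})
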