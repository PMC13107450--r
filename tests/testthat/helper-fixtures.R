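# Shared fixtures built in code.

default_pulse <- function() pulse_timing(4e-6)

# A Table-2-like parameter set used across kinetics tests.
demo_params <- function(kt_R0 = 1e5, T1 = 500e-6, ...) {
  kinetic_parameters(kt_R0 = kt_R0, T1 = T1, ...)
}

# Simulate the three traces of one dyad (two W protons drawn with the same
# T1, one flavin proton) and fit them globally with shared kt_R0, as the
# study's kinetic analysis does. Returns one column per replicate with the
# geometric mean of the two W relaxation-time estimates (the published W
# value is a single number for the pair), the flavin T1 and the shared
# termination rate.
dyad_recovery_samples <- function(T1_w, T1_f, kt_R0, n_replicates = 50,
                                  n_starts = 2, pulse = default_pulse(),
                                  delays = c(0, 3, 100) * 1e-6,
                                  seed_base = 0) {
  pw <- kinetic_parameters(kt_R0 = kt_R0, T1 = T1_w)
  pf <- kinetic_parameters(kt_R0 = kt_R0, T1 = T1_f)
  vapply(seq_len(n_replicates), function(i) {
    s <- seed_base + 3L * i
    w6 <- gen_kinetic_trace(pw, delays, pulse, seed = s,
                            proton_label = "W6")
    w2 <- gen_kinetic_trace(pw, delays, pulse, seed = s + 1L,
                            proton_label = "W2")
    f8 <- gen_kinetic_trace(pf, delays, pulse, seed = s + 2L,
                            proton_label = "F8'")
    fit <- fit_kinetics(list(w6, w2, f8), pulse,
                        kinetic_fit_spec(shared = "kt_R0",
                                         n_starts = n_starts,
                                         seed = seed_base + i))
    c(T1_w = sqrt(fit$params[[1]]$T1 * fit$params[[2]]$T1),
      T1_f = fit$params[[3]]$T1,
      kt_R0 = fit$params[[1]]$kt_R0)
  }, c(T1_w = 0, T1_f = 0, kt_R0 = 0))
}

dyad_recovery_medians <- function(...) {
  apply(dyad_recovery_samples(...), 1, stats::median)
}

# A flat regular polygon with optional Gaussian coordinate noise; returns a
# labeled_frame with the polygon as both masks offset in z (for simple
# plane/centroid tests).
polygon_frame <- function(n = 6, radius = 1.4, dz = 3.5, noise = 0,
                          rng = NULL) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  ring <- cbind(radius * cos(ang), radius * sin(ang), 0)
  if (noise > 0) {
    eps <- if (is.null(rng)) stats::rnorm(2 * 3 * n, 0, noise) else
      rng(stats::rnorm, 2 * 3 * n, 0, noise)
    ring1 <- ring + matrix(eps[seq_len(3 * n)], ncol = 3)
    ring2 <- ring + matrix(eps[3 * n + seq_len(3 * n)], ncol = 3)
  } else {
    ring1 <- ring
    ring2 <- ring
  }
  ring2[, 3] <- ring2[, 3] + dz
  labeled_frame(atom_names = c(paste0("F", seq_len(n)), paste0("W", seq_len(n))),
                coordinates = rbind(ring1, ring2),
                f_mask = seq_len(n), w_mask = n + seq_len(n))
}

# Random rigid transform applied to all coordinates of a frame.
apply_rigid <- function(frame, R, shift) {
  frame$coordinates <- frame$coordinates %*% t(R) +
    matrix(shift, nrow(frame$coordinates), 3, byrow = TRUE)
  frame
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
         3, 3, byrow = TRUE)
}
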