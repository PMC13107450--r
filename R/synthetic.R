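# Synthetic-data generators. Every generator draws from its own seeded
# random stream (never the global one) and attaches a `truth` record
# sufficient to recompute the noiseless signal exactly.

#' Generate a noisy CIDNP kinetic trace with known truth
#'
#' Simulates the cyclic-photoreaction model at the given delay design and
#' adds Gaussian noise. The two designs used in practice are three delays
#' (0, 3, 100 us) read out with a 4 us detection pulse and ten delays over
#' 0-100 us with a 2 us pulse.
#'
#' @param params True [kinetic_parameters()].
#' @param delays Delay design (s); default `c(0, 3, 100) * 1e-6`.
#' @param pulse [pulse_timing()]; default 4 us.
#' @param noise_level Noise level; default 0.05 (5 % relative).
#' @param noise_model `"gaussian_relative"` (sd = level x |model|) or
#'   `"gaussian_absolute"` (sd = level).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @param proton_label Label for the trace.
#' @return A [kinetic_trace()] with attribute `truth` (list: `params`,
#'   `pulse`, `noiseless`).
#' @export
gen_kinetic_trace <- function(params, delays = c(0, 3, 100) * 1e-6,
                              pulse = pulse_timing(4e-6),
                              noise_level = 0.05,
                              noise_model = c("gaussian_relative",
                                              "gaussian_absolute"),
                              seed = 1, proton_label = "sim") {
  noise_model <- match.arg(noise_model)
  stopifnot(noise_level >= 0)
  clean <- simulate_observed_kinetics(params, delays, pulse,
                                      proton_label = proton_label)
  rng <- local_rng(seed)
  eps <- rng(stats::rnorm, length(delays))
  noisy <- switch(noise_model,
    gaussian_relative = clean$intensities +
      noise_level * abs(clean$intensities) * eps,
    gaussian_absolute = clean$intensities + noise_level * eps)
  out <- kinetic_trace(proton_label, clean$times, noisy)
  attr(out, "truth") <- list(params = params, pulse = pulse,
                             noiseless = clean$intensities,
                             noise_level = noise_level,
                             noise_model = noise_model, seed = seed)
  out
}

# Default 30-point logarithmic field grid, 1 mT - 9.4 T.
default_field_grid <- function(n_fields = 30, field_range = c(1e-3, 9.4)) {
  10^seq(log10(field_range[1]), log10(field_range[2]), length.out = n_fields)
}

#' Generate synthetic field-cycling profiles with a known mechanism
#'
#' Builds per-proton field profiles carrying the signature of one mechanism:
#' `J_BIRADICAL` - a log-normal-shaped uniformly emissive peak at the truth
#' peak field with negligible high-field tail; `DG_INTERMOLECULAR` - a
#' sigmoidal onset above ~1 T with per-proton signs (mixed by construction);
#' `LOWFIELD_HFC` - nucleus-specific signed peaks below the hyperfine field
#' scale; `NONE` - flat noise. The peak/sigmoid shapes are modelling
#' inventions for classifier testing, not measured line shapes.
#'
#' @param mechanism One of `"J_BIRADICAL"`, `"DG_INTERMOLECULAR"`,
#'   `"LOWFIELD_HFC"`, `"NONE"`.
#' @param protons Proton labels (>= 2).
#' @param peak_field J-resonance peak field (tesla) for `J_BIRADICAL`; `NA`
#'   draws it log-uniformly in 5-20 mT.
#' @param snr Peak signal-to-noise ratio per proton (>= 0; 0 = noiseless).
#' @param n_fields,field_range Field grid (default 30 log-spaced points,
#'   1 mT - 9.4 T).
#' @param conformer_class Class tag attached to the profiles.
#' @param seed Integer seed.
#' @return List of [field_profile()] objects with attribute `truth`.
#' @export
gen_field_profiles <- function(mechanism = c("J_BIRADICAL",
                                             "DG_INTERMOLECULAR",
                                             "LOWFIELD_HFC", "NONE"),
                               protons = c("F8'", "W6", "W2", "W4"),
                               peak_field = NA_real_,
                               snr = 10,
                               n_fields = 30, field_range = c(1e-3, 9.4),
                               conformer_class = "unassigned",
                               seed = 1) {
  mechanism <- match.arg(mechanism)
  if (length(protons) < 2) stop("need >= 2 protons")
  stopifnot(snr >= 0)
  fields <- default_field_grid(n_fields, field_range)
  lf <- log10(fields)
  rng <- local_rng(seed)

  width <- 0.25 # dex, log-normal peak width
  if (mechanism == "J_BIRADICAL" && is.na(peak_field)) {
    peak_field <- 10^(rng(stats::runif, 1, log10(5e-3), log10(20e-3)))
  }
  if (mechanism == "J_BIRADICAL" &&
      (peak_field < field_range[1] || peak_field > field_range[2])) {
    stop("peak field outside the field grid")
  }

  amps <- exp(rng(stats::rnorm, length(protons), 0, 0.15))
  signs <- switch(mechanism,
    J_BIRADICAL = rep(-1, length(protons)),           # uniform emissive
    DG_INTERMOLECULAR = mixed_signs(rng, length(protons)),
    LOWFIELD_HFC = mixed_signs(rng, length(protons)),
    NONE = rep(0, length(protons)))
  lowfield_peak <- 10^(rng(stats::runif, 1, log10(1.2e-3), log10(3e-3)))

  clean <- lapply(seq_along(protons), function(j) {
    switch(mechanism,
      J_BIRADICAL = signs[j] * amps[j] *
        exp(-(lf - log10(peak_field))^2 / (2 * width^2)),
      DG_INTERMOLECULAR = signs[j] * amps[j] /
        (1 + exp(-(lf - log10(2)) / 0.2)),
      LOWFIELD_HFC = signs[j] * amps[j] *
        exp(-(lf - log10(lowfield_peak))^2 / (2 * 0.2^2)),
      NONE = rep(0, n_fields))
  })

  profiles <- lapply(seq_along(protons), function(j) {
    sd <- if (snr > 0) amps[j] / snr else 0
    noisy <- clean[[j]] + sd * rng(stats::rnorm, n_fields)
    field_profile(protons[j], fields, noisy, conformer_class)
  })
  attr(profiles, "truth") <- list(
    mechanism = mechanism,
    peak_field = if (mechanism == "J_BIRADICAL") peak_field else NA_real_,
    lowfield_peak = if (mechanism == "LOWFIELD_HFC") lowfield_peak else NA_real_,
    amplitudes = amps, signs = signs, snr = snr, seed = seed,
    clean = clean, fields = fields)
  profiles
}

# Random +/-1 vector guaranteed to contain both signs.
mixed_signs <- function(rng, n) {
  s <- sign(rng(stats::runif, n) - 0.5)
  s[s == 0] <- 1
  if (length(unique(s)) == 1) s[1] <- -s[1]
  s
}

#' Generate a labeled conformer ensemble with controlled motif fractions
#'
#' Builds frames from template flavin/tryptophan ring geometries placed at
#' sampled distances and orientations. Each frame is drawn to be exactly one
#' of: stacked (satisfies [is_stacked()] by construction, no hydrogen bond),
#' hydrogen-bonded (satisfies [is_hbond()] by construction, not stacked), or
#' extended (neither; center distances 9-14 angstrom). Proline omega
#' dihedrals are realised near 0 deg (cis) or 180 deg (trans) according to
#' the drawn label, so [label_frame()] recovers the generating label.
#'
#' @param n_frames Number of frames, >= 1.
#' @param stacked_fraction,hbond_fraction Motif probabilities, exclusive
#'   (sum <= 1).
#' @param label_probs Named probability vector over cis/trans codes (equal
#'   lengths, characters T/C, position 1 nearest the flavin). Default:
#'   uniform over the 8 three-proline codes.
#' @param criteria [geometry_criteria()] the construction must satisfy.
#' @param seed Integer seed.
#' @return An object of class `conformer_ensemble`: list of `frames`, the
#'   `truth` data.frame (`frame`, `label`, `class`), and the generating
#'   fractions.
#' @export
gen_conformer_ensemble <- function(n_frames,
                                   stacked_fraction = 0.20,
                                   hbond_fraction = 0.05,
                                   label_probs = NULL,
                                   criteria = geometry_criteria(),
                                   seed = 1) {
  stopifnot(n_frames >= 1, stacked_fraction >= 0, hbond_fraction >= 0)
  if (stacked_fraction + hbond_fraction > 1) {
    stop("stacked_fraction + hbond_fraction must be <= 1 (exclusive classes)")
  }
  if (is.null(label_probs)) {
    codes <- apply(expand.grid(rep(list(c("T", "C")), 3)), 1, paste,
                   collapse = "")
    label_probs <- stats::setNames(rep(1 / 8, 8), codes)
  }
  if (is.null(names(label_probs)) ||
      !all(grepl("^[TC]+$", names(label_probs))) ||
      length(unique(nchar(names(label_probs)))) != 1) {
    stop("label_probs must be named with equal-length strings over {T, C}")
  }
  label_probs <- label_probs / sum(label_probs)
  n_pro <- nchar(names(label_probs)[1])
  rng <- local_rng(seed)

  u <- rng(stats::runif, n_frames)
  cls <- ifelse(u < stacked_fraction, "stacked",
                ifelse(u < stacked_fraction + hbond_fraction, "hbond",
                       "extended"))
  labels <- names(label_probs)[
    rng(sample.int, length(label_probs), n_frames, replace = TRUE,
        prob = label_probs)]

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    frames[[i]] <- build_dyad_frame(cls[i], labels[i], rng, criteria)
  }
  structure(list(frames = frames,
                 truth = data.frame(frame = seq_len(n_frames),
                                    label = labels, class = cls,
                                    stringsAsFactors = FALSE),
                 stacked_fraction = stacked_fraction,
                 hbond_fraction = hbond_fraction,
                 label_probs = label_probs, n_prolines = n_pro,
                 seed = seed),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "Synthetic conformer ensemble: %d frames (%d prolines), truth fractions stacked %.3g / hbond %.3g\n",
    length(x$frames), x$n_prolines, x$stacked_fraction, x$hbond_fraction))
  invisible(x)
}

# --- frame construction helpers ------------------------------------------

ring_template <- function(radius = 1.39) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_, a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
           a[2] * a[1] * C + a[3] * s_, a[2]^2 * C + c_, a[2] * a[3] * C - a[1] * s_,
           a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, a[3]^2 * C + c_),
         3, 3, byrow = TRUE)
}

random_rotation <- function(rng) {
  repeat {
    q <- rng(stats::rnorm, 4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
         3, 3, byrow = TRUE)
}

# Place point D at distance `len` from C, with angle(B, C, D) = ang_deg and
# dihedral(A, B, C, D) = dih_deg (natural extension reference frame).
place_by_internal <- function(A, B, C, len, ang_deg, dih_deg) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  ang <- ang_deg * pi / 180
  dih <- dih_deg * pi / 180
  d <- c(-len * cos(ang), len * sin(ang) * cos(dih), len * sin(ang) * sin(dih))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# One synthetic dyad frame: a planar 6-ring flavin surrogate with a carbonyl
# oxygen acceptor at the origin, a planar 6-ring tryptophan surrogate with an
# in-plane N-H donor, and one 4-atom chain per proline realising the omega
# dihedral. The W placement realises the requested structural class exactly
# (verified, with redraws of the free orientation angles if an accidental
# second motif appears).
build_dyad_frame <- function(class, label, rng, criteria) {
  f_ring <- ring_template()
  f_O <- c(1.39 + 1.23, 0, 0)        # carbonyl O on ring atom 1
  w_ring <- ring_template()
  w_N <- c(1.39 + 1.35, 0, 0)
  w_H <- c(1.39 + 1.35 + 1.01, 0, 0)

  for (attempt in 1:200) {
    if (class == "stacked") {
      d <- rng(stats::runif, 1, criteria$stack_dmin + 0.2,
               criteria$stack_dmax - 0.3)
      th <- rng(stats::runif, 1, 0, criteria$stack_angle_lo - 10)
      if (rng(stats::runif, 1) < 0.5) th <- 180 - th
      spin <- rng(stats::runif, 1, 0, 360)
      R <- rotation_matrix(c(0, 0, 1), spin) %*%
        rotation_matrix(c(1, 0, 0), th)
      center <- c(0, 0, d)
    } else if (class == "hbond") {
      # linear N-H...O geometry aimed at the carbonyl oxygen
      u <- c(cos(pi / 6), sin(pi / 6), 0)    # 150 deg off the O-C direction
      spin <- rng(stats::runif, 1, 0, 360)
      H_t <- f_O + 1.9 * u
      N_t <- H_t + 1.01 * u
      center <- N_t + (1.39 + 1.35) * u
      # the template's ring-to-N-to-H axis (+x) maps onto -u so that N and H
      # land on the constructed linear N-H...O geometry; spin about the
      # donor axis is free
      R <- rotation_matrix(u, spin) %*% align_rotation(c(1, 0, 0), -u)
    } else {
      d <- rng(stats::runif, 1, 9, 14)
      dir <- rng(stats::rnorm, 3)
      dir <- dir / sqrt(sum(dir^2))
      center <- d * dir
      R <- random_rotation(rng)
    }

    w_atoms <- rbind(w_ring, w_N, w_H) %*% t(R)
    w_atoms <- sweep(w_atoms, 2, center, `+`)

    # proline omega chains, placed well away from the chromophores
    omega_atoms <- NULL
    omega_quads <- list()
    n_pro <- nchar(label)
    omegas <- numeric(n_pro)
    for (k in seq_len(n_pro)) {
      tgt <- substr(label, k, k)
      repeat {
        om <- if (tgt == "C") rng(stats::rnorm, 1, 0, 6) else
          180 - rng(stats::rnorm, 1, 0, 6)
        om <- ((om + 180) %% 360) - 180
        if (om == -180) om <- 180
        if (classify_cis_trans(om, criteria) == tgt) break
      }
      omegas[k] <- om
      off <- c(0, 25 + 10 * k, 0)
      A <- off + c(-1.52 * 0.5, 1.52 * sqrt(3) / 2, 0)
      B <- off
      C <- off + c(1.33, 0, 0)
      D <- place_by_internal(A, B, C, 1.46, 120, om)
      base <- 15 + 4 * (k - 1)   # after 7 flavin + 8 tryptophan atoms
      omega_atoms <- rbind(omega_atoms, A, B, C, D)
      omega_quads[[k]] <- base + 1:4
    }

    coords <- rbind(f_ring, f_O, w_atoms, omega_atoms)
    atom_names <- c(paste0("C", 1:6, "F"), "O1F",
                    paste0("C", 1:6, "W"), "N1W", "H1W",
                    unlist(lapply(seq_len(n_pro), function(k) {
                      paste0("P", k, c("CA", "C", "N", "CA2"))
                    })))
    residues <- c(rep("FLV", 7), rep("TRP", 8),
                  rep(paste0("PRO", seq_len(n_pro)), each = 4))
    fr <- labeled_frame(atom_names, coords,
                        f_mask = 1:6, w_mask = 8:13,
                        donor_quads = matrix(c(14L, 15L, 7L, 1L), 1),
                        omega_quads = omega_quads,
                        residue_labels = residues)

    dd <- moiety_center_distance(fr)
    tt <- interplane_angle(fr)
    ok <- switch(class,
      stacked = is_stacked(dd, tt, criteria) && !is_hbond(fr, criteria = criteria),
      hbond = is_hbond(fr, criteria = criteria) && !is_stacked(dd, tt, criteria),
      extended = !is_stacked(dd, tt, criteria) && !is_hbond(fr, criteria = criteria))
    if (ok && label_frame(fr, criteria) == label) return(fr)
  }
  stop("failed to construct a '", class, "' frame after 200 attempts")
}

# Rotation taking unit vector `from` to unit vector `to`.
align_rotation <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(from * to)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular axis
    perp <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * from) * from
    return(rotation_matrix(axis, 180))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Generate a synthetic Stejskal-Tanner diffusion decay
#'
#' Default design: 16 linearly incremented gradients spanning 2-95 % of
#' 50 G/cm, Delta = 50 ms, delta = 2 ms, 1 % relative Gaussian noise.
#'
#' @param D True diffusion coefficient (m^2/s).
#' @param I0 True zero-gradient intensity.
#' @param gradients Gradient amplitudes (T/m).
#' @param big_delta,little_delta Timing parameters (s).
#' @param noise_level Relative Gaussian noise level (default 0.01).
#' @param gyromagnetic_ratio Nuclear gyromagnetic ratio (default 1H).
#' @param seed Integer seed.
#' @return A [diffusion_decay()] with attribute `truth`.
#' @export
gen_diffusion_decay <- function(D = 5e-10, I0 = 1,
                                gradients = seq(0.02, 0.95, length.out = 16) * 0.5,
                                big_delta = 50e-3, little_delta = 2e-3,
                                noise_level = 0.01,
                                gyromagnetic_ratio = .gamma_1H,
                                seed = 1) {
  stopifnot(D > 0, I0 > 0, noise_level >= 0)
  b <- (gyromagnetic_ratio * gradients * little_delta)^2 *
    (big_delta - little_delta / 3)
  clean <- I0 * exp(-D * b)
  rng <- local_rng(seed)
  noisy <- clean * (1 + noise_level * rng(stats::rnorm, length(b)))
  out <- diffusion_decay(gradients, noisy, big_delta, little_delta,
                         gyromagnetic_ratio = gyromagnetic_ratio)
  attr(out, "truth") <- list(D = D, I0 = I0, noiseless = clean,
                             noise_level = noise_level, seed = seed)
  out
}
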