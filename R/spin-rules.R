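# Physical constants (CODATA 2018).
.bohr_magneton <- 9.2740100783e-24   # J/T
.planck_h <- 6.62607015e-34          # J s
.g_electron <- 2.0023                # free-electron g-factor (rounded)

#' Radical-pair configuration for the CIDNP sign rules
#'
#' @param sgn_delta_g Sign (+1/-1) of the electron g-factor difference.
#' @param sgn_a Sign (+1/-1) of the hyperfine coupling of the nucleus.
#' @param mu +1 for a triplet precursor, -1 for a singlet precursor.
#' @param eps +1 for geminate recombination products, -1 for escape products.
#' @param sgn_J Sign of the exchange interaction J_ex (+1, -1, or 0 when not
#'   applicable).
#' @param J_abs Optional magnitude of J_ex, >= 0, in the unit given by
#'   `J_unit`.
#' @param J_unit `"J"` (energy) or `"Hz"` (frequency, converted via Planck's
#'   constant).
#' @param g Electron g-factor (dimensionless).
#' @return An object of class `radical_pair_config`.
#' @export
radical_pair_config <- function(sgn_delta_g, sgn_a, mu, eps, sgn_J = 0,
                                J_abs = NULL, J_unit = c("J", "Hz"),
                                g = .g_electron) {
  J_unit <- match.arg(J_unit)
  for (v in list(sgn_delta_g = sgn_delta_g, sgn_a = sgn_a, mu = mu, eps = eps)) {
    if (!v %in% c(-1, 1)) stop("sgn_delta_g, sgn_a, mu, eps must be +1 or -1")
  }
  if (!sgn_J %in% c(-1, 0, 1)) stop("sgn_J must be -1, 0 or +1")
  if (!is.null(J_abs) && (!is.finite(J_abs) || J_abs < 0)) {
    stop("J_abs must be >= 0")
  }
  if (!is.finite(g) || g <= 0) stop("g must be > 0")
  structure(list(sgn_delta_g = sgn_delta_g, sgn_a = sgn_a, mu = mu, eps = eps,
                 sgn_J = sgn_J, J_abs = J_abs, J_unit = J_unit, g = g),
            class = "radical_pair_config")
}

#' Kaptein sign rule for the high-field (delta-g dominated) regime
#'
#' Gamma = sgn(delta g) x sgn(a) x mu x eps. Gamma = +1 predicts absorptive,
#' Gamma = -1 emissive polarization for the nucleus.
#'
#' @param config A [radical_pair_config()].
#' @return +1 or -1.
#' @export
kaptein_high_field_sign <- function(config) {
  stopifnot(inherits(config, "radical_pair_config"))
  config$sgn_delta_g * config$sgn_a * config$mu * config$eps
}

#' Sign rule at the exchange-dominated J resonance (level anticrossing)
#'
#' Gamma = sgn(J_ex) x mu x eps. Independent of the hyperfine sign, so every
#' nucleus of the pair acquires the same polarization sign - the fingerprint
#' of biradical (exchange-coupled) CIDNP.
#'
#' @param config A [radical_pair_config()] with `sgn_J != 0`.
#' @return +1 or -1.
#' @export
j_resonance_sign <- function(config) {
  stopifnot(inherits(config, "radical_pair_config"))
  if (config$sgn_J == 0) {
    stop("J-resonance sign rule not applicable: sgn_J is 0")
  }
  config$sgn_J * config$mu * config$eps
}

#' Level-anticrossing field for a given exchange interaction
#'
#' B_LAC ~ |J_ex| / (g mu_B): the field at which the S and T+/- electron
#' levels of an exchange-coupled pair anticross, where hyperfine-induced
#' singlet-triplet mixing (and hence CIDNP) is maximal.
#'
#' @param J_abs Magnitude of the exchange interaction, >= 0.
#' @param unit `"J"` (energy) or `"Hz"` (frequency; converted via h). Note
#'   `J_abs` in Hz means |J_ex|/h.
#' @param g Electron g-factor.
#' @return B_LAC in tesla.
#' @examples
#' lac_field(280.2e6, unit = "Hz") # ~ 10 mT
#' @export
lac_field <- function(J_abs, unit = c("J", "Hz"), g = .g_electron) {
  unit <- match.arg(unit)
  if (any(!is.finite(J_abs)) || any(J_abs < 0)) stop("J_abs must be >= 0")
  J <- if (unit == "Hz") J_abs * .planck_h else J_abs
  J / (g * .bohr_magneton)
}

#' Exchange interaction corresponding to a level-anticrossing field
#'
#' Exact inverse of [lac_field()]: |J_ex| = g mu_B B.
#'
#' @param B Magnetic field (tesla), >= 0.
#' @param unit Unit of the returned magnitude, `"J"` or `"Hz"`.
#' @param g Electron g-factor.
#' @return |J_ex| in the requested unit.
#' @export
j_from_field <- function(B, unit = c("J", "Hz"), g = .g_electron) {
  unit <- match.arg(unit)
  if (any(!is.finite(B)) || any(B < 0)) stop("B must be >= 0")
  J <- B * g * .bohr_magneton
  if (unit == "Hz") J / .planck_h else J
}

#' Classify the magnetic-field regime of a radical pair
#'
#' Deterministic banding of the field axis by comparison with the hyperfine
#' field scale and the exchange field |J_ex|/(g mu_B): `LOW_HFC` where the
#' electron Zeeman energy is comparable to the hyperfine coupling (polarization
#' sign is nucleus-specific), `INTERMEDIATE_J` where it matches the exchange
#' interaction while far exceeding the hyperfine scale (J-resonance, uniform
#' sign), `HIGH_DG` in the delta-g dominated high field, `GAP` in between
#' (where neither mechanism is effective). "Comparable" means within
#' `sim_factor` (default 3) and "far exceeds" at least `gg_factor`
#' (default 10); the delta-g regime additionally requires
#' `B >= dg_field_min` (default 1 T).
#'
#' @param B Field (tesla), > 0.
#' @param a_scale Hyperfine field scale (tesla), > 0.
#' @param J_field Exchange field |J_ex|/(g mu_B) (tesla), > 0.
#' @param sim_factor,gg_factor,dg_field_min Comparison constants.
#' @return One of `"LOW_HFC"`, `"INTERMEDIATE_J"`, `"GAP"`, `"HIGH_DG"`.
#' @export
classify_field_regime <- function(B, a_scale, J_field,
                                  sim_factor = 3, gg_factor = 10,
                                  dg_field_min = 1) {
  stopifnot(all(B > 0), a_scale > 0, J_field > 0)
  vapply(B, function(b) {
    if (b <= sim_factor * a_scale) return("LOW_HFC")
    if (b >= J_field / sim_factor && b <= J_field * sim_factor &&
        b >= gg_factor * a_scale) {
      return("INTERMEDIATE_J")
    }
    if (b >= dg_field_min && b > sim_factor * J_field) return("HIGH_DG")
    "GAP"
  }, "")
}

#' Field-cycling CIDNP profile of one proton
#'
#' @param proton_label Proton name.
#' @param fields Magnetic fields (tesla), strictly increasing, all > 0.
#' @param intensities Signed CIDNP intensities, same length.
#' @param conformer_class `"major"`, `"minor"` or `"unassigned"`.
#' @return An object of class `field_profile`.
#' @export
field_profile <- function(proton_label, fields, intensities,
                          conformer_class = c("unassigned", "major", "minor")) {
  conformer_class <- match.arg(conformer_class)
  fields <- as.numeric(fields)
  intensities <- as.numeric(intensities)
  if (length(fields) != length(intensities)) stop("lengths must match")
  if (any(!is.finite(fields)) || any(fields <= 0)) stop("fields must be > 0")
  if (any(diff(fields) <= 0)) stop("fields must be strictly increasing")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  structure(list(proton_label = as.character(proton_label)[1],
                 conformer_class = conformer_class,
                 fields = fields, intensities = intensities),
            class = "field_profile")
}

#' @export
print.field_profile <- function(x, ...) {
  cat(sprintf("Field profile '%s' (%s): %d points, %.3g-%.3g T\n",
              x$proton_label, x$conformer_class, length(x$fields),
              min(x$fields), max(x$fields)))
  invisible(x)
}

#' Normalize field profiles to a reference field feature
#'
#' Divides every profile by the magnitude of its intensity at the reference
#' field (linear interpolation in log10 B between grid points), as done when
#' comparing concentration series against the J-dominated low-field feature
#' near 10 mT. The reference intensity becomes +/-1 and the operation is
#' idempotent.
#'
#' @param profiles A [field_profile()] or list of them.
#' @param reference_field Reference field (tesla), default 10 mT.
#' @param tol_factor Every profile must have a grid point within
#'   `[reference_field/tol_factor, reference_field*tol_factor]`.
#' @return List of rescaled [field_profile()] objects.
#' @export
normalize_profiles <- function(profiles, reference_field = 0.01,
                               tol_factor = 2) {
  if (inherits(profiles, "field_profile")) profiles <- list(profiles)
  stopifnot(reference_field > 0, tol_factor >= 1)
  lapply(profiles, function(p) {
    stopifnot(inherits(p, "field_profile"))
    near <- p$fields >= reference_field / tol_factor &
      p$fields <= reference_field * tol_factor
    if (!any(near)) {
      stop(sprintf("profile '%s' has no field point within factor %g of %g T",
                   p$proton_label, tol_factor, reference_field))
    }
    ref <- stats::approx(log10(p$fields), p$intensities,
                         xout = log10(reference_field), rule = 2)$y
    if (abs(ref) < 1e-12 * max(abs(p$intensities), 1e-300)) {
      stop(sprintf("normalization degenerate: profile '%s' is ~0 at %g T",
                   p$proton_label, reference_field))
    }
    p$intensities <- p$intensities / abs(ref)
    p
  })
}

# Robust per-profile noise estimate. Two difference-based estimators are
# combined: the 30th percentile of |first differences| (anchored in the
# signal-free part of the grid even when a peak or onset contaminates up to
# ~40% of the differences; for Gaussian noise the 0.30 quantile of |diff|
# equals sqrt(2) qnorm(0.65) sigma) and the median of |second differences|
# (smooth signals curve far less per grid step than noise fluctuates;
# |d2| ~ |N(0, 6 sigma^2)| with median sqrt(6) qnorm(0.75) sigma). The
# smaller of the two is used, floored at half the MAD of the profile so a
# downward-fluctuating order statistic cannot fake significance on a flat
# profile.
profile_noise_sigma <- function(intensities) {
  d1 <- abs(diff(intensities))
  s1 <- unname(stats::quantile(d1, 0.30, type = 7)) /
    (sqrt(2) * stats::qnorm(0.65))
  d2 <- abs(diff(intensities, differences = 2))
  s2 <- stats::median(d2) / (sqrt(6) * stats::qnorm(0.75))
  max(min(s1, s2), 0.5 * stats::mad(intensities))
}

# Strongest interior three-point local maximum of |intensity| whose field
# lies within the window extended by tol_steps grid steps in log10(B).
# Returns NULL if none.
window_extremum <- function(profile, window, tol_steps = 1) {
  f <- profile$fields
  a <- abs(profile$intensities)
  n <- length(f)
  if (n < 3) return(NULL)
  lf <- log10(f)
  step <- stats::median(diff(lf))
  lo <- log10(window[1]) - tol_steps * step
  hi <- log10(window[2]) + tol_steps * step
  idx <- which(seq_len(n) > 1 & seq_len(n) < n & lf >= lo & lf <= hi)
  idx <- idx[a[idx] >= a[idx - 1] & a[idx] >= a[idx + 1] &
               (a[idx] > a[idx - 1] | a[idx] > a[idx + 1])]
  if (length(idx) == 0) return(NULL)
  i <- idx[which.max(a[idx])]
  list(field = f[i], magnitude = a[i], sign = sign(profile$intensities[i]))
}

#' Classify the CIDNP generation mechanism from field-cycling profiles
#'
#' Applies the biradical criteria to a set of per-proton field profiles of
#' one conformer class: (i) the same polarization sign for all observed
#' nuclei, (ii) a pronounced interior extremum of |intensity| inside the
#' J-resonance window (default 5-20 mT, where the level anticrossing of
#' compact conformers falls), (iii) weak or absent response in the high-field
#' delta-g regime (mid-field extremum at least `highfield_ratio` times the
#' maximal |intensity| at B >= `highfield_min`). All three together give
#' `J_BIRADICAL`. Significant high-field signals with nucleus-specific
#' (mixed) signs and no mid-field extremum give `DG_INTERMOLECULAR`;
#' nucleus-specific signs confined below the hyperfine field scale give
#' `LOWFIELD_HFC`; anything else is `NONE`.
#'
#' @param profiles List of >= 2 [field_profile()] objects (one conformer
#'   class).
#' @param window J-resonance search window `c(lo, hi)` in tesla. Window
#'   membership of the detected extremum is tested with a one-grid-step
#'   tolerance in log10(B).
#' @param thresholds Named list overriding any of: `sign_uniformity` (default
#'   1 = strict agreement), `highfield_ratio` (default 3), `floor_mult`
#'   (noise floor for including a proton in the sign count, default 3 robust
#'   sigma), `presence_mult` (floor for calling a feature present, default 5
#'   robust sigma), `highfield_min` (1 T), `lowfield_max` (4 mT).
#' @return An object of class `mechanism_call`: `label`, `peak_field` (tesla,
#'   `NA` unless J-biradical), `sign_uniformity`, `highfield_ratio`,
#'   `evidence_notes`, and a per-profile `details` data.frame.
#' @export
classify_mechanism <- function(profiles, window = c(5e-3, 20e-3),
                               thresholds = list()) {
  if (inherits(profiles, "field_profile")) profiles <- list(profiles)
  if (length(profiles) < 2) {
    stop("insufficient evidence: mechanism classification needs >= 2 profiles")
  }
  stopifnot(length(window) == 2, window[1] > 0, window[2] > window[1])
  th <- utils::modifyList(
    list(sign_uniformity = 1, highfield_ratio = 3, floor_mult = 3,
         presence_mult = 5, highfield_min = 1, lowfield_max = 4e-3),
    thresholds)

  det <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "field_profile"))
    if (window[1] < min(p$fields) || window[2] > max(p$fields)) {
      stop("window must lie within the field range of every profile")
    }
    sig <- profile_noise_sigma(p$intensities)
    a <- abs(p$intensities)
    wx <- window_extremum(p, window)
    hf <- p$fields >= th$highfield_min
    lf <- p$fields <= th$lowfield_max
    hf_i <- if (any(hf)) which(hf)[which.max(a[hf])] else NA_integer_
    lf_i <- if (any(lf)) which(lf)[which.max(a[lf])] else NA_integer_
    data.frame(
      proton = p$proton_label,
      sigma = sig,
      max_abs = max(a),
      significant = max(a) > th$presence_mult * sig,
      peak_in_window = !is.null(wx) &&
        wx$magnitude > th$presence_mult * sig,
      peak_field = if (!is.null(wx)) wx$field else NA_real_,
      peak_mag = if (!is.null(wx)) wx$magnitude else NA_real_,
      peak_sign = if (!is.null(wx)) wx$sign else NA_real_,
      hf_mag = if (!is.na(hf_i)) a[hf_i] else 0,
      hf_sign = if (!is.na(hf_i)) sign(p$intensities[hf_i]) else NA_real_,
      hf_sig = !is.na(hf_i) && a[hf_i] > th$presence_mult * sig,
      lf_mag = if (!is.na(lf_i)) a[lf_i] else 0,
      lf_sign = if (!is.na(lf_i)) sign(p$intensities[lf_i]) else NA_real_,
      lf_sig = !is.na(lf_i) && a[lf_i] > th$presence_mult * sig,
      stringsAsFactors = FALSE)
  })
  det <- do.call(rbind, det)

  sig <- det$significant
  uniformity <- 1
  if (sum(sig) > 0) {
    s <- ifelse(!is.na(det$peak_sign[sig]) & det$peak_in_window[sig],
                det$peak_sign[sig],
                ifelse(det$hf_sig[sig], det$hf_sign[sig], det$lf_sign[sig]))
    s <- s[!is.na(s) & s != 0]
    if (length(s) > 0) uniformity <- max(table(s)) / length(s)
  }
  hf_floor <- max(det$hf_mag, det$sigma)
  hf_ratio <- if (any(sig & det$peak_in_window)) {
    max(det$peak_mag[sig & det$peak_in_window]) / hf_floor
  } else 0

  label <- "NONE"
  peak_field <- NA_real_
  notes <- character(0)
  # criterion (iii) is "weak or absent": satisfied outright when no
  # significant high-field signal exists, otherwise by the amplitude ratio
  weak_highfield <- !any(det$hf_sig) || hf_ratio >= th$highfield_ratio
  if (sum(sig) >= 2 && all(det$peak_in_window[sig]) &&
      uniformity >= th$sign_uniformity && weak_highfield) {
    label <- "J_BIRADICAL"
    peak_field <- stats::median(det$peak_field[sig])
    notes <- sprintf(
      "uniform sign (uniformity %.2f), mid-field extremum at %.3g T, high-field response %.3g x weaker",
      uniformity, peak_field, hf_ratio)
  } else if (sum(det$hf_sig) >= 2 &&
             length(unique(det$hf_sign[det$hf_sig])) > 1 &&
             sum(det$peak_in_window) < 2) {
    label <- "DG_INTERMOLECULAR"
    notes <- "mixed polarization signs at high field, no J-resonance extremum"
  } else if (sum(det$lf_sig) >= 2 &&
             length(unique(det$lf_sign[det$lf_sig])) > 1) {
    label <- "LOWFIELD_HFC"
    notes <- "nucleus-specific signs below the hyperfine field scale"
  } else {
    notes <- "no significant mechanism signature"
  }

  structure(list(label = label, peak_field = peak_field,
                 sign_uniformity = uniformity,
                 highfield_ratio = max(hf_ratio, 0),
                 evidence_notes = paste(notes, collapse = "; "),
                 details = det, thresholds = th, window = window),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Mechanism call: %s\n", x$label))
  if (!is.na(x$peak_field)) cat(sprintf("  peak field      : %.3g T\n", x$peak_field))
  cat(sprintf("  sign uniformity : %.2f\n", x$sign_uniformity))
  cat(sprintf("  high-field ratio: %.3g\n", x$highfield_ratio))
  cat(sprintf("  evidence        : %s\n", x$evidence_notes))
  invisible(x)
}
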