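#' Geometric classification criteria
#'
#' Thresholds for pi-stacking, hydrogen bonds and cis/trans assignment.
#' Stacking: center-center distance within \[`stack_dmin`, `stack_dmax`\]
#' (inclusive) and inter-plane angle below `stack_angle_lo` or above
#' `stack_angle_hi` (strict, treating theta and 180-theta symmetrically).
#' Hydrogen bond: H...O distance below `hbond_dmax` and both the N-H...O and
#' H...O-C angles above `hbond_angle_min` (strict). A proline peptide bond is
#' cis when |omega| < `cis_cut`; the boundary is assigned trans.
#'
#' @param stack_dmin,stack_dmax Stacking distance band (angstrom).
#' @param stack_angle_lo,stack_angle_hi Stacking angle cuts (degrees).
#' @param hbond_dmax H...O distance cut (angstrom).
#' @param hbond_angle_min Angle cut for both hydrogen-bond angles (degrees).
#' @param cis_cut |omega| below which a peptide bond is cis (degrees).
#' @return An object of class `geometry_criteria`.
#' @export
geometry_criteria <- function(stack_dmin = 3.0, stack_dmax = 6.5,
                              stack_angle_lo = 45, stack_angle_hi = 135,
                              hbond_dmax = 3.0, hbond_angle_min = 130,
                              cis_cut = 90) {
  if (!(0 < stack_dmin && stack_dmin < stack_dmax)) {
    stop("need 0 < stack_dmin < stack_dmax")
  }
  if (!(0 < stack_angle_lo && stack_angle_lo < stack_angle_hi &&
        stack_angle_hi < 180)) {
    stop("need 0 < stack_angle_lo < stack_angle_hi < 180")
  }
  if (hbond_dmax <= 0 || hbond_angle_min <= 0 || hbond_angle_min >= 180) {
    stop("invalid hydrogen-bond criteria")
  }
  if (cis_cut <= 0 || cis_cut >= 180) stop("cis_cut must be in (0, 180)")
  structure(list(stack_dmin = stack_dmin, stack_dmax = stack_dmax,
                 stack_angle_lo = stack_angle_lo,
                 stack_angle_hi = stack_angle_hi,
                 hbond_dmax = hbond_dmax, hbond_angle_min = hbond_angle_min,
                 cis_cut = cis_cut),
            class = "geometry_criteria")
}

#' Annotated 3-D coordinate frame of a dyad
#'
#' One frame of a conformer ensemble: coordinates plus the index sets needed
#' by the geometric operators - the flavin ring-system mask (F), the
#' tryptophan indole mask (W), candidate hydrogen-bond quadruples
#' (N, H, O, C-attached-to-O), and, per proline, the four atoms defining the
#' peptide-bond dihedral omega (numbered flavin-first).
#'
#' @param atom_names Character vector of atom names.
#' @param coordinates Numeric n x 3 matrix (angstrom).
#' @param f_mask,w_mask Integer index vectors (>= 3 non-collinear atoms each,
#'   disjoint).
#' @param donor_quads Integer matrix with 4 columns (N, H, O, C), possibly
#'   0 rows.
#' @param omega_quads List of integer 4-vectors, one per proline,
#'   flavin-first order.
#' @param residue_labels Optional character vector of residue labels.
#' @return An object of class `labeled_frame`.
#' @export
labeled_frame <- function(atom_names, coordinates, f_mask, w_mask,
                          donor_quads = matrix(integer(0), ncol = 4),
                          omega_quads = list(),
                          residue_labels = NULL) {
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  if (ncol(coordinates) != 3 || any(!is.finite(coordinates))) {
    stop("coordinates must be a finite n x 3 matrix")
  }
  if (length(atom_names) != n) stop("atom_names length must match coordinates")
  f_mask <- as.integer(f_mask)
  w_mask <- as.integer(w_mask)
  if (length(f_mask) < 3 || length(w_mask) < 3) {
    stop("each moiety mask needs >= 3 atoms")
  }
  idx <- c(f_mask, w_mask, as.integer(donor_quads), unlist(omega_quads))
  if (length(idx) && (any(idx < 1) || any(idx > n))) {
    stop("mask/quad indices out of range")
  }
  if (length(intersect(f_mask, w_mask)) > 0) stop("moiety masks must be disjoint")
  donor_quads <- matrix(as.integer(donor_quads), ncol = 4)
  if (!is.null(residue_labels) && length(residue_labels) != n) {
    stop("residue_labels length must match coordinates")
  }
  structure(list(atom_names = as.character(atom_names),
                 residue_labels = residue_labels,
                 coordinates = coordinates,
                 f_mask = f_mask, w_mask = w_mask,
                 donor_quads = donor_quads, omega_quads = omega_quads),
            class = "labeled_frame")
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat(sprintf(
    "Labeled frame: %d atoms, F mask %d, W mask %d, %d donor quad(s), %d proline(s)\n",
    nrow(x$coordinates), length(x$f_mask), length(x$w_mask),
    nrow(x$donor_quads), length(x$omega_quads)))
  invisible(x)
}

# Signed dihedral (degrees, (-180, 180]) of four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("degenerate geometry: collinear atoms in dihedral")
  }
  m1 <- c(b2[2] * n1[3] - b2[3] * n1[2],
          b2[3] * n1[1] - b2[1] * n1[3],
          b2[1] * n1[2] - b2[2] * n1[1])
  nb2 <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2) / nb2, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Peptide-bond dihedral omega of a proline
#'
#' Standard signed dihedral (degrees, in (-180, 180]) of the four atoms
#' declared in the frame's `omega_quads` for the given proline.
#'
#' @param frame A [labeled_frame()].
#' @param proline_index Which proline (1 = nearest the flavin).
#' @return omega in degrees.
#' @export
omega_dihedral <- function(frame, proline_index) {
  stopifnot(inherits(frame, "labeled_frame"))
  if (proline_index < 1 || proline_index > length(frame$omega_quads)) {
    stop("no omega quad defined for proline ", proline_index)
  }
  q <- frame$omega_quads[[proline_index]]
  x <- frame$coordinates
  dihedral_angle(x[q[1], ], x[q[2], ], x[q[3], ], x[q[4], ])
}

#' Classify a peptide bond as cis or trans
#'
#' `"C"` iff |omega| < `cis_cut` (default 90 deg), else `"T"`; the boundary
#' maps to trans.
#'
#' @param omega Dihedral angle(s) in degrees.
#' @param criteria A [geometry_criteria()].
#' @return Character vector of `"C"`/`"T"`.
#' @export
classify_cis_trans <- function(omega, criteria = geometry_criteria()) {
  ifelse(abs(omega) < criteria$cis_cut, "C", "T")
}

#' Cis/trans label string of a frame
#'
#' Applies [classify_cis_trans()] to every proline omega of the frame,
#' flavin-first, e.g. `"CTT"`.
#'
#' @param frame A [labeled_frame()].
#' @param criteria A [geometry_criteria()].
#' @return A single string over `{T, C}` of length = number of prolines.
#' @export
label_frame <- function(frame, criteria = geometry_criteria()) {
  stopifnot(inherits(frame, "labeled_frame"))
  n <- length(frame$omega_quads)
  if (n == 0) stop("frame declares no proline omega quads")
  omegas <- vapply(seq_len(n), function(i) omega_dihedral(frame, i), 1.0)
  paste(classify_cis_trans(omegas, criteria), collapse = "")
}

#' Distance between the geometric centers of the F and W moieties
#'
#' Euclidean distance between the unweighted centroids of the two moiety
#' masks (angstrom).
#'
#' @param frame A [labeled_frame()].
#' @return Distance in angstrom.
#' @export
moiety_center_distance <- function(frame) {
  stopifnot(inherits(frame, "labeled_frame"))
  cf <- colMeans(frame$coordinates[frame$f_mask, , drop = FALSE])
  cw <- colMeans(frame$coordinates[frame$w_mask, , drop = FALSE])
  sqrt(sum((cf - cw)^2))
}

# Total-least-squares plane normal of a point set (unit vector along the
# smallest principal direction). Errors on (near-)collinear sets.
plane_normal <- function(xyz) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(xyz)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)) {
    stop("degenerate geometry: mask atoms are collinear, no plane definable")
  }
  sv$v[, 3]
}

#' Angle between the F and W plane normals
#'
#' Fits a total-least-squares plane through each moiety mask and returns the
#' angle between the two normals, folded to \[0, 180\] degrees. Values near 0
#' or 180 both indicate parallel (stackable) rings; the stacking criterion
#' treats them symmetrically.
#'
#' @param frame A [labeled_frame()].
#' @return Angle in degrees.
#' @export
interplane_angle <- function(frame) {
  stopifnot(inherits(frame, "labeled_frame"))
  nf <- plane_normal(frame$coordinates[frame$f_mask, , drop = FALSE])
  nw <- plane_normal(frame$coordinates[frame$w_mask, , drop = FALSE])
  cosang <- sum(nf * nw)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Pi-stacking test
#'
#' TRUE iff the center distance lies in the stacking band (inclusive) and the
#' inter-plane angle is below `stack_angle_lo` or above `stack_angle_hi`
#' (near-parallel rings).
#'
#' @param d Center-center distance (angstrom), >= 0.
#' @param theta Inter-plane angle (degrees, in \[0, 180\]).
#' @param criteria A [geometry_criteria()].
#' @return Logical.
#' @examples
#' is_stacked(5.0, 10)  # TRUE
#' is_stacked(5.0, 90)  # FALSE (T-shaped)
#' @export
is_stacked <- function(d, theta, criteria = geometry_criteria()) {
  stopifnot(all(d >= 0), all(theta >= 0), all(theta <= 180))
  d >= criteria$stack_dmin & d <= criteria$stack_dmax &
    (theta < criteria$stack_angle_lo | theta > criteria$stack_angle_hi)
}

#' Hydrogen-bond test for one donor quadruple
#'
#' TRUE iff the H...O distance is below `hbond_dmax` and both the N-H...O and
#' H...O-C angles exceed `hbond_angle_min`.
#'
#' @param frame A [labeled_frame()].
#' @param quad Integer 4-vector (N, H, O, C) of atom indices; defaults to the
#'   rows of `frame$donor_quads` (any row qualifying returns TRUE).
#' @param criteria A [geometry_criteria()].
#' @return Logical.
#' @export
is_hbond <- function(frame, quad = NULL, criteria = geometry_criteria()) {
  stopifnot(inherits(frame, "labeled_frame"))
  quads <- if (is.null(quad)) frame$donor_quads else
    matrix(as.integer(quad), ncol = 4)
  if (nrow(quads) == 0) return(FALSE)
  if (any(quads < 1) || any(quads > nrow(frame$coordinates))) {
    stop("hydrogen-bond quad indices out of range")
  }
  x <- frame$coordinates
  for (i in seq_len(nrow(quads))) {
    q <- quads[i, ]
    N <- x[q[1], ]; H <- x[q[2], ]; O <- x[q[3], ]; C <- x[q[4], ]
    if (any(!is.finite(H))) stop("missing hydrogen coordinates")
    d_ho <- sqrt(sum((H - O)^2))
    if (d_ho >= criteria$hbond_dmax) next
    if (vertex_angle(N, H, O) <= criteria$hbond_angle_min) next
    if (vertex_angle(H, O, C) <= criteria$hbond_angle_min) next
    return(TRUE)
  }
  FALSE
}

#' Per-conformer geometric statistics of an ensemble
#'
#' Computes, for every frame, the cis/trans label, F-W center distance,
#' inter-plane angle, stacking and hydrogen-bond flags; aggregates them into
#' per-label conditional probabilities P(stacked | label), P(hbond | label),
#' per-label distance/angle histograms (Freedman-Diaconis bins on a common
#' break set) and the pooled "Sum" distribution, which equals the
#' label-population-weighted mixture of the per-label densities.
#'
#' @param frames A list of [labeled_frame()] objects or a
#'   `conformer_ensemble` from [gen_conformer_ensemble()].
#' @param criteria A [geometry_criteria()].
#' @return An object of class `ensemble_statistics`: `per_frame` data.frame,
#'   `by_label` data.frame (`label`, `n`, `weight`, `p_stacked`, `p_hbond`),
#'   and `densities` (per label and `"Sum"`, for `distance` and `angle`).
#' @export
ensemble_statistics <- function(frames, criteria = geometry_criteria()) {
  if (inherits(frames, "conformer_ensemble")) frames <- frames$frames
  if (length(frames) == 0) stop("empty ensemble")
  per <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    d <- moiety_center_distance(fr)
    th <- interplane_angle(fr)
    data.frame(frame = i,
               label = label_frame(fr, criteria),
               distance = d, angle = th,
               stacked = is_stacked(d, th, criteria),
               hbond = is_hbond(fr, criteria = criteria),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)

  labs <- sort(unique(per$label))
  by_label <- do.call(rbind, lapply(labs, function(l) {
    s <- per[per$label == l, ]
    data.frame(label = l, n = nrow(s), weight = nrow(s) / nrow(per),
               p_stacked = mean(s$stacked), p_hbond = mean(s$hbond),
               stringsAsFactors = FALSE)
  }))

  fd_breaks <- function(x) {
    if (length(unique(x)) == 1) return(c(x[1] - 0.5, x[1] + 0.5))
    nb <- max(1, grDevices::nclass.FD(x))
    seq(min(x), max(x), length.out = nb + 1)
  }
  densities <- list()
  for (what in c("distance", "angle")) {
    breaks <- fd_breaks(per[[what]])
    per_lab <- lapply(c(labs, "Sum"), function(l) {
      x <- if (l == "Sum") per[[what]] else per[[what]][per$label == l]
      h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                          include.lowest = TRUE, right = TRUE)
      list(mids = h$mids, density = h$density, counts = h$counts)
    })
    names(per_lab) <- c(labs, "Sum")
    densities[[what]] <- list(breaks = breaks, by_label = per_lab)
  }

  structure(list(per_frame = per, by_label = by_label, densities = densities,
                 criteria = criteria),
            class = "ensemble_statistics")
}

#' @export
print.ensemble_statistics <- function(x, ...) {
  cat(sprintf("Ensemble statistics over %d frames\n", nrow(x$per_frame)))
  df <- x$by_label
  df$weight <- round(df$weight, 4)
  df$p_stacked <- round(df$p_stacked, 4)
  df$p_hbond <- round(df$p_hbond, 4)
  print(df, row.names = FALSE)
  cat(sprintf("Pooled: P(stacked) = %.4f, P(hbond) = %.4f\n",
              mean(x$per_frame$stacked), mean(x$per_frame$hbond)))
  invisible(x)
}

#' Energy difference per atom between two conformer distributions
#'
#' |mean_a - mean_b| / n_atoms, in kcal/mol per atom; used to judge whether
#' conformer energy distributions are close enough for coexistence.
#'
#' @param mean_a,mean_b Mean energies (kcal/mol).
#' @param n_atoms Number of atoms, > 0.
#' @return kcal/mol per atom.
#' @examples
#' per_atom_energy_difference(26, 0, 108) # ~0.24
#' @export
per_atom_energy_difference <- function(mean_a, mean_b, n_atoms) {
  if (!is.finite(n_atoms) || n_atoms <= 0) stop("n_atoms must be > 0")
  abs(mean_a - mean_b) / n_atoms
}
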