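# Proton gyromagnetic ratio (rad s^-1 T^-1).
.gamma_1H <- 2.6752218744e8

#' Pulsed-field-gradient diffusion decay
#'
#' Signal intensities from a bipolar-gradient stimulated-echo experiment at a
#' series of gradient amplitudes, with the diffusion time Delta and gradient
#' duration delta needed by the Stejskal-Tanner attenuation law.
#'
#' @param gradients Gradient amplitudes, ascending, >= 0; at least 4 points.
#' @param intensities Signal intensities (arbitrary units), same length.
#' @param big_delta Diffusion time Delta (s).
#' @param little_delta Gradient duration delta (s), < `big_delta`.
#' @param gradient_unit `"T_per_m"` or `"G_per_cm"` (1 G/cm = 0.01 T/m;
#'   converted on construction).
#' @param gyromagnetic_ratio Nuclear gyromagnetic ratio (rad s^-1 T^-1),
#'   default 1H.
#' @return An object of class `diffusion_decay` (gradients stored in T/m).
#' @export
diffusion_decay <- function(gradients, intensities, big_delta, little_delta,
                            gradient_unit = c("T_per_m", "G_per_cm"),
                            gyromagnetic_ratio = .gamma_1H) {
  gradient_unit <- match.arg(gradient_unit)
  gradients <- as.numeric(gradients)
  intensities <- as.numeric(intensities)
  if (gradient_unit == "G_per_cm") gradients <- gradients * 1e-2
  if (length(gradients) < 4) stop("a diffusion decay needs >= 4 points")
  if (length(intensities) != length(gradients)) stop("lengths must match")
  if (any(!is.finite(gradients)) || any(gradients < 0)) {
    stop("gradients must be >= 0")
  }
  if (any(diff(gradients) <= 0)) stop("gradients must be strictly ascending")
  if (!(little_delta > 0 && big_delta > little_delta)) {
    stop("need 0 < little_delta < big_delta")
  }
  if (gyromagnetic_ratio <= 0) stop("gyromagnetic_ratio must be > 0")
  structure(list(gradients = gradients, intensities = intensities,
                 big_delta = big_delta, little_delta = little_delta,
                 gyromagnetic_ratio = gyromagnetic_ratio),
            class = "diffusion_decay")
}

# Stejskal-Tanner b-factor (s/m^2) for each gradient amplitude.
st_b_factor <- function(decay) {
  (decay$gyromagnetic_ratio * decay$gradients * decay$little_delta)^2 *
    (decay$big_delta - decay$little_delta / 3)
}

#' Stejskal-Tanner monoexponential fit of a diffusion decay
#'
#' Fits I(g) = I0 exp(-D gamma^2 g^2 delta^2 (Delta - delta/3)) by nonlinear
#' least squares (Levenberg-Marquardt), started from the log-linear
#' regression of log I on the b-factor.
#'
#' @param decay A [diffusion_decay()] with positive intensities.
#' @return An object of class `stejskal_tanner_fit`: `D` (m^2/s), `I0`,
#'   `stderr_D`, `stderr_I0`, `residual_norm`, `converged`.
#' @export
stejskal_tanner_fit <- function(decay) {
  stopifnot(inherits(decay, "diffusion_decay"))
  if (any(decay$intensities <= 0)) {
    stop("intensities must be positive for the monoexponential fit")
  }
  b <- st_b_factor(decay)
  if (max(b) - min(b) <= 0) {
    stop("D undetermined: no gradient variation in the decay")
  }
  lin <- stats::lm(log(decay$intensities) ~ b)
  D0 <- -unname(stats::coef(lin)[2])
  I00 <- exp(unname(stats::coef(lin)[1]))
  if (D0 <= 0) {
    stop(sprintf("fit-domain error: data do not decay (linearized D = %.3g)",
                 D0))
  }
  fit <- minpack.lm::nls.lm(
    par = c(logI0 = log(I00), logD = log(D0)),
    fn = function(p) decay$intensities - exp(p[1]) * exp(-exp(p[2]) * b),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  I0 <- exp(fit$par[[1]])
  D <- exp(fit$par[[2]])
  # asymptotic errors on the natural scale via the delta method
  se <- tryCatch({
    covl <- stats::vcov(fit)
    c(I0 * sqrt(covl[1, 1]), D * sqrt(covl[2, 2]))
  }, error = function(e) c(NA_real_, NA_real_))
  structure(list(D = D, I0 = I0, stderr_D = se[2], stderr_I0 = se[1],
                 residual_norm = fit$deviance,
                 converged = fit$info %in% 1:4,
                 n_points = length(b)),
            class = "stejskal_tanner_fit")
}

#' @export
print.stejskal_tanner_fit <- function(x, ...) {
  cat(sprintf("Stejskal-Tanner fit: D = %.4g +/- %.2g m^2/s, I0 = %.4g, RSS = %.3g\n",
              x$D, x$stderr_D, x$I0, x$residual_norm))
  invisible(x)
}

#' Compare the diffusion coefficients of two species
#'
#' Ratio D_first / D_second with first-order propagated uncertainty. A ratio
#' above 1 flags the first species as the faster-diffusing (more compact)
#' one, as expected for a cis-containing minor conformer versus the extended
#' major form.
#'
#' @param fit_first,fit_second [stejskal_tanner_fit()] results (converged).
#' @return List with `ratio`, `stderr`, `first_more_compact`.
#' @export
compare_species <- function(fit_first, fit_second) {
  stopifnot(inherits(fit_first, "stejskal_tanner_fit"),
            inherits(fit_second, "stejskal_tanner_fit"))
  if (!fit_first$converged || !fit_second$converged) {
    stop("both fits must have converged")
  }
  ratio <- fit_first$D / fit_second$D
  rel <- sqrt((fit_first$stderr_D / fit_first$D)^2 +
                (fit_second$stderr_D / fit_second$D)^2)
  list(ratio = ratio, stderr = ratio * rel, first_more_compact = ratio > 1)
}
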