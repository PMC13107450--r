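#' Parameters of the cyclic-photoreaction CIDNP model
#'
#' Container for the kinetic parameters of the cyclic photoreaction that
#' generates CIDNP in a dye/quencher radical system: pseudo-first-order
#' radical termination (`kt_R0` = k_t * R_0), nuclear paramagnetic relaxation
#' in the radical (`T1`), geminate polarization amplitude (`P_G`), the
#' F-pair-to-geminate polarization ratio (`gamma`, beta * R_0 = gamma * P_G by
#' construction), and a detector scaling factor. An absolute initial radical
#' concentration `R0` is accepted only for simulating concentrations; the
#' observable depends on k_t and R_0 only through their product.
#'
#' @param kt_R0 Pseudo-first-order termination rate k_t * R_0 (s^-1), > 0.
#' @param T1 Nuclear paramagnetic relaxation time (s), > 0.
#' @param P_G Geminate polarization amplitude (arbitrary polarization units).
#' @param gamma Ratio of F-pair to geminate polarization, in [0, 3]. For a
#'   triplet precursor the theoretical value is 3; the default 2.8 accounts
#'   for incomplete reversibility of the photoreaction.
#' @param scale Detector scaling factor (arbitrary), > 0.
#' @param R0 Optional initial radical concentration (mol/L), > 0.
#'
#' @return An object of class `kinetic_parameters`.
#' @examples
#' kinetic_parameters(kt_R0 = 1e5, T1 = 500e-6)
#' @export
kinetic_parameters <- function(kt_R0, T1, P_G = 1, gamma = 2.8, scale = 1,
                               R0 = NULL) {
  vals <- c(kt_R0 = kt_R0, T1 = T1, P_G = P_G, gamma = gamma, scale = scale)
  if (!all(is.finite(vals))) {
    stop("kinetic parameters must be finite: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (kt_R0 <= 0) stop("kt_R0 must be > 0")
  if (T1 <= 0) stop("T1 must be > 0")
  if (scale <= 0) stop("scale must be > 0")
  if (gamma < 0 || gamma > 3) stop("gamma must lie in [0, 3]")
  if (!is.null(R0) && (!is.finite(R0) || R0 <= 0)) stop("R0 must be > 0")
  structure(list(kt_R0 = kt_R0, T1 = T1, P_G = P_G, gamma = gamma,
                 scale = scale, R0 = R0),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Cyclic-photoreaction kinetic parameters\n")
  cat(sprintf("  kt*R0 : %.4g s^-1\n", x$kt_R0))
  cat(sprintf("  T1    : %.4g s (%.3g us)\n", x$T1, x$T1 * 1e6))
  cat(sprintf("  P_G   : %.4g   gamma: %.3g   scale: %.4g\n",
              x$P_G, x$gamma, x$scale))
  if (!is.null(x$R0)) cat(sprintf("  R0    : %.4g mol/L\n", x$R0))
  invisible(x)
}

#' One proton's CIDNP intensity versus post-flash delay
#'
#' @param proton_label Proton name, e.g. `"W2"` or `"F8'"`.
#' @param times Detection times after the laser flash (s), strictly
#'   increasing, >= 0, at least 3 points.
#' @param intensities Signal intensities (arbitrary units), same length.
#' @param sigma Optional per-point noise estimates, same length, > 0.
#'
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(proton_label, times, intensities, sigma = NULL) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) < 3) stop("a kinetic trace needs at least 3 time points")
  if (length(intensities) != length(times)) {
    stop("times and intensities must have equal length")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and >= 0 (time zero = laser flash)")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(times)) stop("sigma length must match times")
    if (any(!is.finite(sigma) | sigma <= 0)) stop("sigma must be > 0")
  }
  structure(list(proton_label = as.character(proton_label)[1], times = times,
                 intensities = intensities, sigma = sigma),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("CIDNP kinetic trace '%s': %d points, %.3g-%.3g us\n",
              x$proton_label, length(x$times),
              min(x$times) * 1e6, max(x$times) * 1e6))
  invisible(x)
}

#' Detection-pulse timing
#'
#' The effective detection time of a spectrum acquired with a rectangular RF
#' pulse is taken as the pulse center, so the model is evaluated at
#' delay + duration/2.
#'
#' @param rf_pulse_duration RF detection-pulse duration (s), >= 0.
#' @return An object of class `pulse_timing` with fields `rf_pulse_duration`
#'   and `effective_offset` (= duration/2).
#' @examples
#' pulse_timing(4e-6)$effective_offset # 2 us
#' @export
pulse_timing <- function(rf_pulse_duration) {
  if (!is.finite(rf_pulse_duration) || rf_pulse_duration < 0) {
    stop("rf_pulse_duration must be finite and >= 0")
  }
  structure(list(rf_pulse_duration = rf_pulse_duration,
                 effective_offset = rf_pulse_duration / 2),
            class = "pulse_timing")
}

#' Relative radical concentration R(t)/R_0
#'
#' Closed-form solution of the second-order termination law
#' dR/dt = -k_t R^2: R(t) = R_0 / (1 + k_t R_0 t). Returned relative to R_0;
#' multiplied by `R0` if the parameter set carries an absolute concentration.
#'
#' @param params A [kinetic_parameters()] object.
#' @param t Time(s) after the flash (s), >= 0; vectorised.
#' @return Radical concentration, in (0, 1] relative units (or mol/L when
#'   `params$R0` is set), monotone non-increasing in `t`.
#' @examples
#' p <- kinetic_parameters(kt_R0 = 1e5, T1 = 5e-4)
#' radical_concentration(p, c(0, 10e-6, 30e-6)) # 1, 0.5, 0.25
#' @export
radical_concentration <- function(params, t) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  rel <- 1 / (1 + params$kt_R0 * t)
  if (!is.null(params$R0)) rel * params$R0 else rel
}

# Right-hand side of the coupled polarization equations, relative radical
# units: y = (P_R, P), r(t) = 1/(1 + k t),
#   dP_R/dt = -k r P_R - k gamma P_G r^2 - P_R/T1
#   dP/dt   = +k r P_R + k gamma P_G r^2
polarization_rhs <- function(t, y, parms) {
  r <- 1 / (1 + parms[["k"]] * t)
  pump <- parms[["k"]] * parms[["gPG"]] * r * r
  transfer <- parms[["k"]] * r * y[1]
  list(c(-transfer - pump - y[1] * parms[["T1inv"]], transfer + pump))
}

#' Integrate the coupled nuclear-polarization equations
#'
#' Solves the two coupled ODEs for the nuclear polarization carried by the
#' radicals (`P_R`) and accumulated in diamagnetic recombination products
#' (`P`), driven by the analytic second-order radical decay. Spin sorting in
#' F-pair encounters creates polarization `+beta` per recombining pair in the
#' products and `-beta` in the surviving radicals; radical-borne polarization
#' additionally relaxes with `T1`.
#'
#' @param params A [kinetic_parameters()] object.
#' @param t_grid Ascending time grid starting at 0 (s).
#' @param initial_conditions Numeric pair `c(P_R0, P0)`. The default
#'   convention is `P_R(0) = -P_G` (spin-sorting anti-phase polarization in
#'   escaped radicals) and `P(0) = +P_G` (geminate product polarization).
#' @param rtol,atol Integrator tolerances (adaptive stiff-capable `lsoda`).
#' @param compiled Use the compiled right-hand side (default); the pure-R
#'   implementation is retained for cross-checking.
#' @return A data.frame with columns `time`, `P_R`, `P`.
#' @export
integrate_polarization <- function(params, t_grid,
                                   initial_conditions = c(-params$P_G, params$P_G),
                                   rtol = 1e-8, atol = 1e-12,
                                   compiled = TRUE) {
  stopifnot(inherits(params, "kinetic_parameters"))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1 || t_grid[1] != 0) stop("t_grid must start at 0")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly ascending")
  ic <- as.numeric(initial_conditions)
  if (length(ic) != 2 || any(!is.finite(ic))) {
    stop("initial_conditions must be a finite pair (P_R(0), P(0))")
  }
  parms <- c(k = params$kt_R0, T1inv = 1 / params$T1,
             gPG = params$gamma * params$P_G)
  sol <- if (compiled) {
    deSolve::ode(y = ic, times = t_grid, func = "cidnp_polarization_rhs",
                 parms = parms, dllname = "cidnpdyad",
                 initfunc = "cidnp_polarization_init", nout = 0,
                 rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y = ic, times = t_grid, func = polarization_rhs,
                 parms = parms, rtol = rtol, atol = atol)
  }
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop(sprintf(
      "polarization integration failed (istate %d) for kt_R0 = %g, T1 = %g",
      diag[1], params$kt_R0, params$T1))
  }
  out <- as.data.frame(unclass(sol))
  names(out) <- c("time", "P_R", "P")
  out
}

# Product polarization P at arbitrary times >= 0 (not necessarily sorted),
# with unit geminate polarization absorbed into params$P_G.
polarization_at <- function(params, t_eval, rtol = 1e-8, atol = 1e-12) {
  grid <- sort(unique(c(0, t_eval)))
  sol <- integrate_polarization(params, grid, rtol = rtol, atol = atol)
  sol$P[match(t_eval, grid)]
}

# Product polarization for several independent parameter sets evaluated on
# per-set time vectors in one stacked compiled solve (cost of a joint fit's
# residual evaluation is then one solver call). Returns a list of P vectors.
.multi_max_pairs <- 16L

polarization_at_multi <- function(par_list, times_list,
                                  rtol = 1e-8, atol = 1e-12) {
  m <- length(par_list)
  if (m > .multi_max_pairs) {
    # chunk large joint problems
    idx <- split(seq_len(m), ceiling(seq_len(m) / .multi_max_pairs))
    return(do.call(c, lapply(idx, function(i) {
      polarization_at_multi(par_list[i], times_list[i], rtol, atol)
    })))
  }
  grid <- sort(unique(c(0, unlist(times_list))))
  triples <- unlist(lapply(par_list, function(p) {
    c(p$kt_R0, 1 / p$T1, p$gamma * p$P_G)
  }))
  parms <- numeric(1 + 3 * .multi_max_pairs)
  parms[1] <- m
  parms[1 + seq_along(triples)] <- triples
  y0 <- as.numeric(rbind(-vapply(par_list, `[[`, 1.0, "P_G"),
                         vapply(par_list, `[[`, 1.0, "P_G")))
  sol <- deSolve::ode(y = y0, times = grid,
                      func = "cidnp_polarization_multi_rhs", parms = parms,
                      dllname = "cidnpdyad",
                      initfunc = "cidnp_polarization_multi_init", nout = 0,
                      rtol = rtol, atol = atol)
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop(sprintf("joint polarization integration failed (istate %d)", diag[1]))
  }
  lapply(seq_len(m), function(j) {
    P <- sol[, 1 + 2 * j]
    P[match(times_list[[j]], grid)]
  })
}

#' Simulate the observed CIDNP kinetic trace
#'
#' Evaluates the product polarization at each delay shifted by the effective
#' detection offset (pulse center) and applies the detector scaling factor.
#'
#' @param params A [kinetic_parameters()] object.
#' @param delays Programmed delays after the laser flash (s), >= 0.
#' @param pulse A [pulse_timing()] object.
#' @param proton_label Label attached to the returned trace.
#' @param rtol,atol Integrator tolerances.
#' @return A [kinetic_trace()] whose `times` are the programmed delays and
#'   whose intensities are `scale * P(delay + pulse$effective_offset)`.
#' @examples
#' p <- kinetic_parameters(kt_R0 = 1e5, T1 = 500e-6)
#' simulate_observed_kinetics(p, c(0, 3e-6, 100e-6), pulse_timing(4e-6))
#' @export
simulate_observed_kinetics <- function(params, delays, pulse,
                                       proton_label = "sim",
                                       rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(pulse, "pulse_timing"))
  delays <- as.numeric(delays)
  if (length(delays) == 0) stop("delays must contain at least one value")
  if (any(!is.finite(delays)) || any(delays < 0)) stop("delays must be >= 0")
  p_vals <- polarization_at(params, delays + pulse$effective_offset,
                            rtol = rtol, atol = atol)
  kinetic_trace(proton_label, delays, params$scale * p_vals)
}

# Exact T1 -> infinity solution of the product polarization (conservation of
# P + P_R): P(t) = P_G (1 + gamma log(1 + k t)) / (1 + k t) for the default
# initial conditions. Used as an independent oracle for the integrator.
polarization_closed_form_no_relax <- function(params, t) {
  u <- params$kt_R0 * t
  params$P_G * (1 + params$gamma * log1p(u)) / (1 + u)
}
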