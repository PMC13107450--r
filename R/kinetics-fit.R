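#' Specification of a kinetic fit
#'
#' Declares which model parameters are free, which are shared across traces,
#' the parameter bounds, and the multi-start policy. The detector scale enters
#' the model linearly and is profiled out analytically whenever it is free;
#' `P_G` is redundant with `scale` in the observable and is kept fixed at 1.
#'
#' @param free Character subset of `c("kt_R0", "T1", "scale")`.
#' @param shared Character subset of `free` declaring parameters shared
#'   across all traces of a joint fit (e.g. `"kt_R0"`).
#' @param share_groups Named list refining `shared` for partial sharing: for
#'   a parameter name, an integer vector with one group id per trace; traces
#'   with equal ids share that parameter (e.g. `list(T1 = c(1, 1, 2))` ties
#'   the relaxation times of the first two traces, the W6/W2 pair whose
#'   published value is a single number). Parameters listed in `shared`
#'   ignore their group entry.
#' @param fixed Named list of pinned values; recognised names: `gamma`
#'   (default 2.8), `P_G` (default 1), plus any of `kt_R0`, `T1`, `scale`
#'   when not free (defaults 1e5, 1e-4, 1).
#' @param bounds Named list of positive `c(lower, upper)` intervals for the
#'   nonlinear free parameters. Defaults: `kt_R0` in \[1e3, 1e8\] s^-1,
#'   `T1` in \[1e-7, 1e-1\] s.
#' @param n_starts Number of multi-start initialisations (log-uniform within
#'   bounds; the first start sits at the geometric center). Sparse traces
#'   have flat directions, hence the multi-start default of 8.
#' @param seed Integer seed controlling the start points.
#'
#' @return An object of class `kinetic_fit_spec`.
#' @export
kinetic_fit_spec <- function(free = c("kt_R0", "T1", "scale"),
                             shared = character(),
                             share_groups = list(),
                             fixed = list(),
                             bounds = list(),
                             n_starts = 8,
                             seed = 1) {
  allowed <- c("kt_R0", "T1", "scale")
  if (!all(free %in% allowed)) {
    stop("free parameters must be a subset of: ", paste(allowed, collapse = ", "))
  }
  if (!all(shared %in% free)) stop("shared parameters must be free")
  if (!all(names(share_groups) %in% c("kt_R0", "T1"))) {
    stop("share_groups supports the nonlinear parameters kt_R0 and T1")
  }
  fx <- utils::modifyList(
    list(gamma = 2.8, P_G = 1, kt_R0 = 1e5, T1 = 1e-4, scale = 1), fixed)
  bd <- utils::modifyList(
    list(kt_R0 = c(1e3, 1e8), T1 = c(1e-7, 1e-1)), bounds)
  for (nm in names(bd)) {
    b <- bd[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] <= 0 || b[2] <= b[1]) {
      stop("bounds for ", nm, " must be a finite positive interval")
    }
  }
  if (n_starts < 1) stop("n_starts must be >= 1")
  structure(list(free = free, shared = shared, share_groups = share_groups,
                 fixed = fx, bounds = bd,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "kinetic_fit_spec")
}

# Layout of the nonlinear parameter vector (log scale) for a joint fit:
# each entry carries the parameter name and the trace indices it drives
# (all traces for `shared`, a group of traces for `share_groups`, one
# otherwise).
fit_layout <- function(spec, n_traces) {
  nl_names <- intersect(c("kt_R0", "T1"), spec$free)
  entries <- list()
  for (nm in nl_names) {
    if (nm %in% spec$shared) {
      entries[[length(entries) + 1L]] <- list(name = nm,
                                              traces = seq_len(n_traces))
    } else if (nm %in% names(spec$share_groups)) {
      grp <- spec$share_groups[[nm]]
      if (length(grp) != n_traces) {
        stop("share_groups$", nm, " must have one group id per trace")
      }
      for (g in unique(grp)) {
        entries[[length(entries) + 1L]] <- list(name = nm,
                                                traces = which(grp == g))
      }
    } else {
      for (j in seq_len(n_traces)) {
        entries[[length(entries) + 1L]] <- list(name = nm, traces = j)
      }
    }
  }
  entries
}

# Assemble per-trace kinetic parameters from the log-parameter vector.
fit_assemble <- function(theta, layout, spec, n_traces) {
  vals <- lapply(seq_len(n_traces), function(j) {
    list(kt_R0 = spec$fixed$kt_R0, T1 = spec$fixed$T1)
  })
  for (i in seq_along(layout)) {
    e <- layout[[i]]
    v <- exp(theta[i])
    for (j in e$traces) vals[[j]][[e$name]] <- v
  }
  vals
}

# Residuals (optionally weighted) for the joint fit, with scale profiled out
# analytically per trace when free. Returns vector with attributes "scales"
# and "rss".
fit_residuals <- function(theta, layout, spec, traces, pulse, rtol, atol) {
  n_traces <- length(traces)
  vals <- fit_assemble(theta, layout, spec, n_traces)
  par_list <- lapply(vals, function(v) {
    kinetic_parameters(kt_R0 = v$kt_R0, T1 = v$T1, P_G = spec$fixed$P_G,
                       gamma = spec$fixed$gamma, scale = 1)
  })
  times_list <- lapply(traces, function(tr) tr$times + pulse$effective_offset)
  models <- polarization_at_multi(par_list, times_list, rtol, atol)
  res <- vector("list", n_traces)
  scales <- numeric(n_traces)
  for (j in seq_len(n_traces)) {
    tr <- traces[[j]]
    m <- models[[j]]
    w <- if (!is.null(tr$sigma)) 1 / tr$sigma else rep(1, length(m))
    if ("scale" %in% spec$free) {
      denom <- sum((w * m)^2)
      s <- if (denom > 0) sum(w^2 * m * tr$intensities) / denom else 0
    } else {
      s <- spec$fixed$scale
    }
    scales[j] <- s
    res[[j]] <- w * (tr$intensities - s * m)
  }
  out <- unlist(res)
  attr(out, "scales") <- scales
  attr(out, "rss") <- sum(out^2)
  out
}

#' Fit the cyclic-photoreaction model to one or more CIDNP traces
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt on log-parameters,
#' multi-start) recovering `kt_R0`, `T1` and the detector scale from observed
#' kinetic traces. With `shared` parameters declared in the spec, a single
#' joint optimum over all traces is returned (e.g. one `kt_R0` for the dyad,
#' per-proton `T1` and scale). Weighted by `1/sigma` when traces carry noise
#' estimates, unweighted otherwise. Deterministic given `spec$seed`.
#'
#' @param traces A [kinetic_trace()] or list of them.
#' @param pulse A [pulse_timing()] object.
#' @param spec A [kinetic_fit_spec()].
#' @param rtol,atol Integrator tolerances used in the model evaluations.
#' @return An object of class `kinetic_fit` with elements `estimates`
#'   (data.frame: trace, parameter, value, stderr), `residual_norm`,
#'   `n_points`, `n_free`, `converged`, `start_points_used`, and
#'   `params` (list of fitted [kinetic_parameters()] per trace).
#' @export
fit_kinetics <- function(traces, pulse, spec = kinetic_fit_spec(),
                         rtol = 1e-8, atol = 1e-12) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1, inherits(pulse, "pulse_timing"),
            inherits(spec, "kinetic_fit_spec"))
  for (tr in traces) {
    if (!inherits(tr, "kinetic_trace")) stop("traces must be kinetic_trace objects")
    if (all(tr$intensities == 0)) {
      stop("degenerate data: trace '", tr$proton_label, "' is identically zero")
    }
  }
  n_traces <- length(traces)
  layout <- fit_layout(spec, n_traces)
  n_scale <- if ("scale" %in% spec$free) n_traces else 0L
  n_free <- length(layout) + n_scale
  n_points <- sum(vapply(traces, function(t) length(t$times), 1L))
  if (n_points < n_free) {
    stop(sprintf("under-determined fit: %d free parameters but %d data points",
                 n_free, n_points))
  }

  obj <- function(theta) fit_residuals(theta, layout, spec, traces, pulse,
                                       rtol, atol)

  if (length(layout) == 0) {
    # purely linear problem: scale(s) solved directly
    r <- obj(numeric(0))
    theta_best <- numeric(0)
    best <- list(rss = attr(r, "rss"), scales = attr(r, "scales"),
                 converged = TRUE, niter = 0L)
  } else {
    lower <- log(vapply(layout, function(e) spec$bounds[[e$name]][1], 1.0))
    upper <- log(vapply(layout, function(e) spec$bounds[[e$name]][2], 1.0))
    center <- (lower + upper) / 2
    starts <- list(center)
    if (spec$n_starts > 1) {
      rng <- local_rng(spec$seed)
      for (i in seq_len(spec$n_starts - 1L)) {
        starts[[i + 1L]] <- lower + rng(stats::runif, length(lower)) * (upper - lower)
      }
    }
    best <- NULL
    theta_best <- NULL
    for (st in starts) {
      fit <- try(suppressWarnings(minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper,
        fn = function(th) as.numeric(obj(th)),
        control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
      if (inherits(fit, "try-error")) next
      rss <- fit$deviance
      if (is.null(best) || rss < best$rss - 1e-15 * (1 + best$rss)) {
        r <- obj(fit$par)
        best <- list(rss = rss, scales = attr(r, "scales"),
                     converged = fit$info %in% 1:4, niter = fit$niter)
        theta_best <- fit$par
      }
    }
    if (is.null(best)) {
      stop("kinetic fit failed from every start point")
    }
  }

  vals <- fit_assemble(theta_best, layout, spec, n_traces)
  params <- lapply(seq_len(n_traces), function(j) {
    kinetic_parameters(kt_R0 = vals[[j]]$kt_R0, T1 = vals[[j]]$T1,
                       P_G = spec$fixed$P_G, gamma = spec$fixed$gamma,
                       scale = max(best$scales[j], .Machine$double.xmin))
  })

  est <- fit_estimate_table(theta_best, layout, spec, traces, pulse,
                            best, rtol, atol, n_points, n_free)

  structure(list(estimates = est, residual_norm = best$rss,
                 n_points = n_points, n_free = n_free,
                 converged = isTRUE(best$converged),
                 start_points_used = spec$n_starts,
                 params = params),
            class = "kinetic_fit")
}

# Asymptotic standard errors from a forward-difference Jacobian of the
# residuals with respect to the natural (not log) free parameters, with the
# profiled scales treated as free parameters of the full problem.
fit_estimate_table <- function(theta, layout, spec, traces, pulse, best,
                               rtol, atol, n_points, n_free) {
  n_traces <- length(traces)
  vals <- fit_assemble(theta, layout, spec, n_traces)
  rows <- list()
  natural <- numeric(0)
  labels <- character(0)
  trace_of <- integer(0)
  display <- character(0)
  for (i in seq_along(layout)) {
    e <- layout[[i]]
    natural <- c(natural, exp(theta[i]))
    labels <- c(labels, e$name)
    trace_of <- c(trace_of, 0L)
    display <- c(display,
                 if (length(e$traces) == n_traces && n_traces > 1) "(shared)"
                 else paste(vapply(e$traces, function(j)
                   traces[[j]]$proton_label, ""), collapse = "+"))
  }
  if ("scale" %in% spec$free) {
    natural <- c(natural, best$scales)
    labels <- c(labels, rep("scale", n_traces))
    trace_of <- c(trace_of, seq_len(n_traces))
    display <- c(display,
                 vapply(traces, function(tr) tr$proton_label, ""))
  }

  resid_at <- function(x) {
    vv <- vals
    k <- 0
    for (i in seq_along(layout)) {
      k <- k + 1
      e <- layout[[i]]
      for (j in e$traces) vv[[j]][[e$name]] <- x[k]
    }
    scales <- if ("scale" %in% spec$free) x[k + seq_len(n_traces)] else
      rep(spec$fixed$scale, n_traces)
    par_list <- lapply(vv, function(v) {
      kinetic_parameters(kt_R0 = max(v$kt_R0, 1e-300),
                         T1 = max(v$T1, 1e-300),
                         P_G = spec$fixed$P_G, gamma = spec$fixed$gamma,
                         scale = 1)
    })
    times_list <- lapply(traces, function(tr) tr$times + pulse$effective_offset)
    models <- polarization_at_multi(par_list, times_list, rtol, atol)
    out <- lapply(seq_len(n_traces), function(j) {
      tr <- traces[[j]]
      w <- if (!is.null(tr$sigma)) 1 / tr$sigma else rep(1, length(models[[j]]))
      w * (tr$intensities - scales[j] * models[[j]])
    })
    unlist(out)
  }

  se <- rep(NA_real_, length(natural))
  dof <- n_points - n_free
  if (length(natural) > 0 && dof > 0) {
    r0 <- resid_at(natural)
    J <- matrix(0, length(r0), length(natural))
    for (k in seq_along(natural)) {
      h <- max(abs(natural[k]), 1e-12) * 1e-6
      xk <- natural
      xk[k] <- xk[k] + h
      J[, k] <- (resid_at(xk) - r0) / h
    }
    # column equilibration: parameter scales span many orders of magnitude
    cn <- sqrt(colSums(J^2))
    ok <- cn > 0
    s2 <- sum(r0^2) / dof
    if (any(ok)) {
      Jn <- J[, ok, drop = FALSE] %*% diag(1 / cn[ok], sum(ok))
      cov <- try(solve(crossprod(Jn)), silent = TRUE)
      if (!inherits(cov, "try-error")) {
        d <- diag(cov)
        se[ok] <- ifelse(d > 0, sqrt(s2 * d) / cn[ok], NA_real_)
      }
    }
  }

  data.frame(trace = display,
             parameter = labels, value = natural, stderr = se,
             stringsAsFactors = FALSE)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit: %d points, %d free parameters, RSS = %.4g%s\n",
              x$n_points, x$n_free, x$residual_norm,
              if (x$converged) "" else " (NOT converged)"))
  df <- x$estimates
  df$value <- signif(df$value, 5)
  df$stderr <- signif(df$stderr, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Profile a parameter's identifiability
#'
#' Refits the remaining free parameters with one parameter pinned at each
#' grid value, returning the residual norm along the grid. For identifiable
#' parameters the profile rises away from the optimum; for parameters outside
#' the kinetic window (e.g. `T1` far beyond the last delay) it stays flat.
#'
#' @param traces A [kinetic_trace()] or list of them.
#' @param pulse A [pulse_timing()] object.
#' @param spec A [kinetic_fit_spec()]; `parameter` must be free in it.
#' @param parameter One of `"kt_R0"`, `"T1"`.
#' @param grid Values (within bounds) at which to pin `parameter`.
#' @return data.frame with columns `value`, `residual_norm`, `converged`.
#' @export
profile_identifiability <- function(traces, pulse, spec, parameter, grid) {
  stopifnot(parameter %in% c("kt_R0", "T1"))
  if (!parameter %in% spec$free) stop(parameter, " is not free in the spec")
  grid <- as.numeric(grid)
  if (length(grid) == 0) {
    return(data.frame(value = numeric(0), residual_norm = numeric(0),
                      converged = logical(0)))
  }
  b <- spec$bounds[[parameter]]
  if (any(grid < b[1] | grid > b[2])) stop("grid values must lie within bounds")
  out <- lapply(grid, function(v) {
    sp <- spec
    sp$free <- setdiff(sp$free, parameter)
    sp$shared <- setdiff(sp$shared, parameter)
    sp$fixed[[parameter]] <- v
    fit <- try(fit_kinetics(traces, pulse, sp), silent = TRUE)
    if (inherits(fit, "try-error")) {
      stop("profile refit failed at ", parameter, " = ", v, ": ",
           attr(fit, "condition")$message)
    }
    data.frame(value = v, residual_norm = fit$residual_norm,
               converged = fit$converged)
  })
  do.call(rbind, out)
}
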