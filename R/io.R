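# Readers and writers for the tab-separated interchange formats: '#'-prefixed
# comment headers carry metadata, required column headers are checked, and
# malformed rows are reported with their line numbers.

read_tsv_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(lines[ln], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[ln]))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body_idx <- setdiff(seq_along(lines), meta_lines)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) < 2) stop(path, ": no data rows")
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    stop(path, ": missing required column(s): ", paste(missing, collapse = ", "))
  }
  rows <- lapply(body_idx[-1], function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) {
      stop(sprintf("%s:%d: expected %d fields, found %d", path, ln,
                   length(header), length(f)))
    }
    f
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!any(is.na(v))) df[[j]] <- v
  }
  list(data = df, meta = meta)
}

write_tsv_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    writeLines(paste(vapply(df[i, ], function(x) {
      if (is.numeric(x)) format(x, digits = 17) else as.character(x)
    }, ""), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write CIDNP kinetic traces
#'
#' Tab-separated files with columns `time_us`, `intensity` and optional
#' `sigma`; times are stored in microseconds on disk and converted to
#' seconds on read. A `# proton_label:` comment names the proton; a long
#' format with a `proton_label` column holding several traces is also
#' accepted (a list is then returned).
#'
#' @param path File path.
#' @return A [kinetic_trace()] (or list of them for long format).
#' @export
read_trace <- function(path) {
  tab <- read_tsv_table(path, required = c("time_us", "intensity"))
  df <- tab$data
  if (!is.numeric(df$time_us) || !is.numeric(df$intensity)) {
    stop(path, ": time_us and intensity must be numeric")
  }
  build <- function(d, label) {
    kinetic_trace(label, d$time_us * 1e-6, d$intensity,
                  sigma = if ("sigma" %in% names(d)) d$sigma else NULL)
  }
  if ("proton_label" %in% names(df)) {
    labs <- unique(df$proton_label)
    out <- lapply(labs, function(l) build(df[df$proton_label == l, ], l))
    names(out) <- labs
    if (length(out) == 1) out[[1]] else out
  } else {
    build(df, tab$meta$proton_label %||% "unknown")
  }
}

#' @rdname read_trace
#' @param trace A [kinetic_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  df <- data.frame(time_us = trace$times * 1e6, intensity = trace$intensities)
  if (!is.null(trace$sigma)) df$sigma <- trace$sigma
  write_tsv_table(df, path, meta = list(proton_label = trace$proton_label,
                                        time_unit = "us"))
}

#' Read / write field-cycling profile sets
#'
#' Tab-separated files with a `field_T` column followed by one signed
#' intensity column per proton; the conformer class is carried in a
#' `# conformer_class:` comment line.
#'
#' @param path File path.
#' @return A list of [field_profile()] objects.
#' @export
read_profiles <- function(path) {
  tab <- read_tsv_table(path, required = "field_T")
  df <- tab$data
  if (!is.numeric(df$field_T)) stop(path, ": field_T must be numeric")
  if (any(diff(df$field_T) <= 0)) {
    stop(path, ": field_T column must be strictly increasing")
  }
  cls <- tab$meta$conformer_class %||% "unassigned"
  protons <- setdiff(names(df), "field_T")
  if (length(protons) == 0) stop(path, ": no proton intensity columns")
  out <- lapply(protons, function(p) {
    if (!is.numeric(df[[p]])) stop(path, ": column ", p, " must be numeric")
    field_profile(p, df$field_T, df[[p]], cls)
  })
  names(out) <- protons
  out
}

#' @rdname read_profiles
#' @param profiles List of [field_profile()] objects on a common field grid.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "field_profile")) profiles <- list(profiles)
  f0 <- profiles[[1]]$fields
  for (p in profiles) {
    if (!isTRUE(all.equal(p$fields, f0))) {
      stop("all profiles must share one field grid to be written together")
    }
  }
  df <- data.frame(field_T = f0)
  for (p in profiles) df[[p$proton_label]] <- p$intensities
  write_tsv_table(df, path,
                  meta = list(conformer_class = profiles[[1]]$conformer_class,
                              field_unit = "T"))
}

#' Read / write diffusion decays
#'
#' Tab-separated files with columns `gradient`, `intensity`; the timing
#' parameters and gradient unit travel in comment headers
#' (`# big_delta_s:`, `# little_delta_s:`, `# gradient_unit:` = `T_per_m`
#' or `G_per_cm`).
#'
#' @param path File path.
#' @return A [diffusion_decay()].
#' @export
read_decay <- function(path) {
  tab <- read_tsv_table(path, required = c("gradient", "intensity"))
  df <- tab$data
  bd <- as.numeric(tab$meta$big_delta_s %||% NA)
  ld <- as.numeric(tab$meta$little_delta_s %||% NA)
  if (is.na(bd) || is.na(ld)) {
    stop(path, ": comment headers big_delta_s and little_delta_s are required")
  }
  unit <- tab$meta$gradient_unit %||% "T_per_m"
  if (!unit %in% c("T_per_m", "G_per_cm")) {
    stop(path, ": unknown gradient_unit '", unit, "'")
  }
  diffusion_decay(df$gradient, df$intensity, bd, ld, gradient_unit = unit)
}

#' @rdname read_decay
#' @param decay A [diffusion_decay()].
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "diffusion_decay"))
  write_tsv_table(data.frame(gradient = decay$gradients,
                             intensity = decay$intensities),
                  path,
                  meta = list(big_delta_s = format(decay$big_delta, digits = 17),
                              little_delta_s = format(decay$little_delta, digits = 17),
                              gradient_unit = "T_per_m"))
}

# --- coordinate readers ---------------------------------------------------

# Multi-frame XYZ: repeated blocks of (atom count, comment, atom lines).
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) <= length(lines)]
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop(sprintf("%s:%d: expected an atom count", path, i))
    if (i + 1 + n > length(lines)) {
      stop(sprintf("%s:%d: truncated frame (%d atoms declared)", path, i, n))
    }
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4)
    if (length(bad) > 0) {
      stop(sprintf("%s:%d: malformed atom line", path, i + 1 + bad[1]))
    }
    nm <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      stop(sprintf("%s: non-numeric coordinates in frame starting line %d", path, i))
    }
    frames[[length(frames) + 1]] <- list(atom_names = nm, coordinates = xyz)
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop(path, ": no frames found")
  frames
}

# PDB with MODEL/ENDMDL blocks via bio3d; a single unnumbered model is
# treated as one frame.
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nm <- pdb$atom$elety
  res <- pdb$atom$resid
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  if (is.null(n_frames)) n_frames <- 1
  lapply(seq_len(n_frames), function(i) {
    co <- matrix(if (is.matrix(xyz)) xyz[i, ] else as.numeric(xyz),
                 ncol = 3, byrow = TRUE)
    list(atom_names = nm, coordinates = co, residue_labels = res)
  })
}

# Mask/selection config: 'key = value' lines, '#' comments. Atom-name lists
# are comma-separated; quadruples are 4 space-separated names, several
# quadruples separated by ';'.
read_masks_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed masks config line: ", ln)
    out[[kv[2]]] <- trimws(kv[3])
  }
  req <- c("f_mask", "w_mask")
  if (!all(req %in% names(out))) {
    stop("masks config must define f_mask and w_mask")
  }
  parse_list <- function(s) trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  parse_quads <- function(s) {
    if (is.null(s) || !nzchar(s)) return(list())
    lapply(trimws(strsplit(s, ";", fixed = TRUE)[[1]]), function(q) {
      nm <- strsplit(trimws(q), "\\s+")[[1]]
      if (length(nm) != 4) stop("quadruple must have 4 atom names: ", q)
      nm
    })
  }
  list(f_mask = parse_list(out$f_mask), w_mask = parse_list(out$w_mask),
       donor_quads = parse_quads(out$donor_quads %||% ""),
       omega_quads = parse_quads(out$omega_quads %||% ""))
}

#' Read a conformer ensemble from multi-frame coordinates
#'
#' Reads a multi-frame XYZ file or a PDB with MODEL/ENDMDL blocks and
#' annotates every frame with the moiety masks, hydrogen-bond quadruples and
#' omega quadruples given by atom name (a masks config file path or an
#' equivalent named list).
#'
#' @param path Coordinate file (`.xyz` or `.pdb`).
#' @param masks Masks config file path, or a list with `f_mask`, `w_mask`
#'   (atom-name vectors) and optional `donor_quads`, `omega_quads` (lists of
#'   4 atom names each).
#' @return List of [labeled_frame()] objects.
#' @export
read_frames <- function(path, masks) {
  if (is.character(masks) && length(masks) == 1) {
    masks <- read_masks_config(masks)
  }
  raw <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    read_xyz_frames(path)
  } else if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    read_pdb_frames(path)
  } else {
    stop("unsupported coordinate format (expect .xyz or .pdb): ", path)
  }
  lapply(raw, function(fr) {
    name_index <- function(nms) {
      idx <- match(nms, fr$atom_names)
      if (any(is.na(idx))) {
        stop("atom name(s) not found in frame: ",
             paste(nms[is.na(idx)], collapse = ", "))
      }
      idx
    }
    dq <- if (length(masks$donor_quads) > 0) {
      do.call(rbind, lapply(masks$donor_quads, name_index))
    } else matrix(integer(0), ncol = 4)
    labeled_frame(fr$atom_names, fr$coordinates,
                  f_mask = name_index(masks$f_mask),
                  w_mask = name_index(masks$w_mask),
                  donor_quads = dq,
                  omega_quads = lapply(masks$omega_quads, name_index),
                  residue_labels = fr$residue_labels)
  })
}

#' Write a conformer ensemble as multi-frame XYZ
#'
#' @param frames List of [labeled_frame()] objects (or a
#'   `conformer_ensemble`).
#' @param path Output path.
#' @export
write_frames_xyz <- function(frames, path) {
  if (inherits(frames, "conformer_ensemble")) frames <- frames$frames
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coordinates)), con)
    writeLines("synthetic dyad frame", con)
    writeLines(sprintf("%s %.8f %.8f %.8f", fr$atom_names,
                       fr$coordinates[, 1], fr$coordinates[, 2],
                       fr$coordinates[, 3]), con)
  }
  invisible(path)
}

# --- pipeline -------------------------------------------------------------

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected so
#' typos fail loudly; the configuration round-trips through JSON unchanged.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param stages Subset of `c("kinetics", "field", "geometry", "diffusion")`.
#' @param kinetics,field,geometry,diffusion Named lists of per-stage options
#'   (see Details in the package vignette).
#' @param out_file Optional path for the JSON report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("kinetics", "field", "geometry",
                                       "diffusion"),
                            kinetics = list(), field = list(),
                            geometry = list(), diffusion = list(),
                            out_file = NULL) {
  allowed <- c("kinetics", "field", "geometry", "diffusion")
  if (!all(stages %in% allowed)) {
    stop("unknown stage(s): ", paste(setdiff(stages, allowed), collapse = ", "))
  }
  check_keys <- function(lst, allowed, what) {
    bad <- setdiff(names(lst), allowed)
    if (length(bad) > 0) {
      stop("unknown ", what, " option(s): ", paste(bad, collapse = ", "))
    }
    lst
  }
  kinetics <- check_keys(kinetics, c("kt_R0", "T1", "gamma", "delays_us",
                                     "pulse_us", "noise_level", "n_replicates"),
                         "kinetics")
  field <- check_keys(field, c("mechanism", "protons", "snr", "window_mT"),
                      "field")
  geometry <- check_keys(geometry, c("n_frames", "stacked_fraction",
                                     "hbond_fraction"), "geometry")
  diffusion <- check_keys(diffusion, c("D", "noise_level"), "diffusion")
  structure(list(seed = as.integer(seed), stages = stages,
                 kinetics = kinetics, field = field, geometry = geometry,
                 diffusion = diffusion, out_file = out_file),
            class = "pipeline_config")
}

#' Run the all-synthetic demonstration pipeline
#'
#' Executes the requested stages end to end with one master seed:
#' synthesize a kinetic trace and refit it, synthesize field profiles and
#' classify the mechanism, synthesize a conformer ensemble and compute its
#' statistics, synthesize a diffusion decay and fit it. Returns one report
#' (and optionally writes it as JSON); reruns with the same configuration
#' are identical.
#'
#' @param config A [pipeline_config()].
#' @return Named list with one block per executed stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("kinetics" %in% config$stages) {
    report$kinetics <- run_stage("kinetics", function() {
      o <- config$kinetics
      pars <- kinetic_parameters(kt_R0 = o$kt_R0 %||% 1e5,
                                 T1 = o$T1 %||% 500e-6,
                                 gamma = o$gamma %||% 2.8)
      pulse <- pulse_timing((o$pulse_us %||% 4) * 1e-6)
      tr <- gen_kinetic_trace(pars,
                              delays = (o$delays_us %||% c(0, 3, 100)) * 1e-6,
                              pulse = pulse,
                              noise_level = o$noise_level %||% 0.05,
                              seed = config$seed)
      fit <- fit_kinetics(tr, pulse, kinetic_fit_spec(seed = config$seed))
      list(truth = list(kt_R0 = pars$kt_R0, T1 = pars$T1),
           estimates = fit$estimates, residual_norm = fit$residual_norm,
           converged = fit$converged)
    })
  }
  if ("field" %in% config$stages) {
    report$field <- run_stage("field", function() {
      o <- config$field
      prof <- gen_field_profiles(mechanism = o$mechanism %||% "J_BIRADICAL",
                                 protons = o$protons %||% c("F8'", "W6", "W2"),
                                 snr = o$snr %||% 10,
                                 seed = config$seed + 1L)
      w <- (o$window_mT %||% c(5, 20)) * 1e-3
      call <- classify_mechanism(prof, window = w)
      list(truth = attr(prof, "truth")$mechanism, label = call$label,
           peak_field = call$peak_field,
           sign_uniformity = call$sign_uniformity,
           highfield_ratio = call$highfield_ratio)
    })
  }
  if ("geometry" %in% config$stages) {
    report$geometry <- run_stage("geometry", function() {
      o <- config$geometry
      ens <- gen_conformer_ensemble(
        n_frames = o$n_frames %||% 500,
        stacked_fraction = o$stacked_fraction %||% 0.20,
        hbond_fraction = o$hbond_fraction %||% 0.05,
        seed = config$seed + 2L)
      st <- ensemble_statistics(ens)
      list(truth = list(stacked = ens$stacked_fraction,
                        hbond = ens$hbond_fraction),
           p_stacked = mean(st$per_frame$stacked),
           p_hbond = mean(st$per_frame$hbond),
           by_label = st$by_label)
    })
  }
  if ("diffusion" %in% config$stages) {
    report$diffusion <- run_stage("diffusion", function() {
      o <- config$diffusion
      dec <- gen_diffusion_decay(D = o$D %||% 5e-10,
                                 noise_level = o$noise_level %||% 0.01,
                                 seed = config$seed + 3L)
      fit <- stejskal_tanner_fit(dec)
      list(truth_D = attr(dec, "truth")$D, D = fit$D, I0 = fit$I0,
           stderr_D = fit$stderr_D)
    })
  }

  if (!is.null(config$out_file)) {
    jsonlite::write_json(report, config$out_file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}
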