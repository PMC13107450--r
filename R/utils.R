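# Internal helpers shared across modules.

# A private random-number stream: returns a sampler that evaluates
# fn(...) (e.g. stats::runif) under its own seeded RNG state, saving and
# restoring the global state so no generator ever leaks global side effects.
local_rng <- function(seed) {
  state <- NULL
  function(fn, ...) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    if (is.null(state)) set.seed(seed) else {
      assign(".Random.seed", state, envir = globalenv())
    }
    out <- fn(...)
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Angle (degrees) at vertex b of the path a-b-c.
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate geometry: coincident atoms in angle")
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
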