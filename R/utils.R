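# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic child seed for stage `k` of a run keyed by `master`.
# Kept below 2^31 so it is always a valid integer seed.
spawn_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + k * 9973) %% 2147483587L)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) {
  trunc(x + 0.5 * sign(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invrisk <- function(...) stop(..., call. = FALSE)

# Earth mean radius (km) used for every great-circle and cell-area
# computation in the package.
EARTH_RADIUS_KM <- 6371.0088
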