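# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single number or NULL")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream-specific child seed so independent stages draw from
# decorrelated streams while staying reproducible from one master seed.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + stream * 1103) %% 2147483647
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name))
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
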