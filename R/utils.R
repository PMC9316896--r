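# Internal helpers shared across modules.

# Run `expr` under a deterministic RNG state without disturbing the caller's
# stream. `seed = NULL` leaves the global stream in charge (still advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed so pipeline stages draw from independent
# streams under one user-facing seed. Kept below 2^31 - 1.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1103L + k * 7919L) %% 2147483629L
}

stop_ftir <- function(class, message, ...) {
  stop(structure(
    class = c(class, "ftirclean_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
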