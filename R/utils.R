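# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state on
# exit. All stochastic generators route through this so no function touches
# global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

check_times <- function(times) {
  if (length(times) == 0L) {
    stop("'times' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times))) {
    stop("'times' must be finite numeric values", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  invisible(as.numeric(times))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
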