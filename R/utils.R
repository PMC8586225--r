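# internal helpers

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# k-sample centred moving average (same length, NA-free interior handled by caller)
moving_average <- function(x, k) {
  n <- length(x)
  if (n < k) stop("series shorter than the averaging window (", k, " samples)")
  cs <- c(0, cumsum(x))
  (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) / k
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar")
  invisible(x)
}
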