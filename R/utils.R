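# internal helpers shared across modules

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All exported functions that consume randomness take an explicit seed and
# route it through here, so no call mutates the global RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# sample standard deviation of the rows of a matrix (n - 1 denominator)
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 columns to compute a standard deviation")
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
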