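# Internal helpers shared across modules.

# Run expr with a private RNG state; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Column standardization to zero mean / unit variance; constant columns -> 0.
standardize_columns <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  z <- sweep(m, 2L, mu, "-")
  keep <- sd > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2L, sd[keep], "/")
  z[, !keep] <- 0
  attr(z, "feature_sd") <- sd
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  invisible(x)
}
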