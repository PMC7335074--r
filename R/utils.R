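# Internal numeric helpers shared across modules.

# Derive independent child seeds from one user seed without touching the
# caller's RNG state more than once. Keeps seeds in 32-bit integer range.
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# average consecutive blocks of `f` rows (exact decimation by block means)
block_mean_rows <- function(m, f) {
  if (f == 1L) return(m)
  n2 <- nrow(m) %/% f
  stopifnot(n2 * f == nrow(m))
  a <- array(m[seq_len(n2 * f), , drop = FALSE], c(f, n2, ncol(m)))
  colMeans(a)
}

# legendre polynomials P0..Pk evaluated on n points mapped to [-1, 1]
legendre_drift <- function(n, order) {
  u <- seq(-1, 1, length.out = n)
  p <- matrix(0, n, order + 1L)
  p[, 1] <- 1
  if (order >= 1) p[, 2] <- u
  if (order >= 2) {
    for (k in 2:order) {
      p[, k + 1] <- ((2 * k - 1) * u * p[, k] - (k - 1) * p[, k - 1]) / k
    }
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
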