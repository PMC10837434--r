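# Internal helpers: seeded evaluation, column standardization, neighbourhoods.

# Evaluate fun() under a fixed RNG seed, restoring global RNG state after.
# All stochastic operations in the package route through this, so no call
# mutates the caller's RNG stream.
withSeed <- function(seed, fun) {
  if (length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fun()
}

# Offsets of the 6-, 18- or 26-connected 3-D neighbourhood.
neighborOffsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  manh <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = manh == 1L,
                 "18" = manh >= 1L & manh <= 2L,
                 "26" = manh >= 1L)
  unname(off[keep, , drop = FALSE])
}

# Column-wise z-scoring with explicit handling of zero-variance columns:
# such columns are flagged and their z-scores set to 0 (association 0).
standardizeColumns <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  C <- M - rep(mu, each = n)
  sdv <- sqrt(colSums(C * C) / (n - 1))
  flagged <- sdv <= 1e-12 * (abs(mu) + 1)
  sdv[flagged] <- 1
  Z <- C / rep(sdv, each = n)
  Z[, flagged] <- 0
  list(z = Z, flagged = flagged)
}

# Column means and sds without scaling (for covariance-method association).
centerColumns <- function(M) {
  n <- nrow(M)
  M - rep(colMeans(M), each = n)
}

isProbability <- function(p) {
  is.numeric(p) && length(p) == 1L && is.finite(p) && p >= 0 && p <= 1
}

isScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
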