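# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (loops, graph search, grid search) and
# never call the code paths they check.

# A compact generator configuration that still hosts all planted regions.
smallConfig <- function(n_subjects = 40, rng_seed = 1, ...) {
  synthConfig(grid_shape = c(12, 18, 12), voxel_size_mm = 3,
              n_subjects = n_subjects, rng_seed = rng_seed, ...)
}

# CohortMatrix from a plain subjects-x-voxels matrix of positive values
# (voxels laid out along the first grid axis).
matrixCohort <- function(X, smoothed = FALSE) {
  V <- ncol(X)
  aff <- diag(4)
  imgs <- lapply(seq_len(nrow(X)), function(i)
    new("GMImage", data = array(X[i, ], c(V, 1, 1)), affine = aff,
        subjectID = sprintf("S%03d", i), smoothed = smoothed))
  buildCohortMatrix(imgs, VoxelGrid(array(1, c(V, 1, 1)), aff))
}

# Brute-force seed-voxel association: scalar cor() per (seed, voxel) pair.
bruteAssoc <- function(X, seeds) {
  out <- matrix(NA_real_, 2, ncol(X))
  for (s in 1:2) for (v in seq_len(ncol(X)))
    out[s, v] <- cor(seeds[, s], X[, v])
  out
}

# Independent connected components via igraph on the voxel adjacency graph.
igraphComponents <- function(mask, connectivity) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  d <- dim(mask)
  ijk <- arrayInd(idx, d)
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  manh <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = manh == 1, "18" = manh >= 1 & manh <= 2,
                    "26" = manh >= 1), ]
  pos <- match(idx, idx)
  lookup <- array(0L, d)
  lookup[idx] <- seq_along(idx)
  edges <- integer(0)
  for (r in seq_len(nrow(off))) {
    ni <- sweep(ijk, 2, as.numeric(off[r, ]), "+")
    ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] & ni[, 2] >= 1 & ni[, 2] <= d[2] &
      ni[, 3] >= 1 & ni[, 3] <= d[3]
    nl <- rep(0L, length(idx))
    nl[ok] <- lookup[ni[ok, , drop = FALSE]]
    src <- which(nl > 0)
    edges <- c(edges, rbind(src, nl[src]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(cid) sort(idx[comp == cid]))
}

# Independent Poisson maximum likelihood by iterative grid refinement
# (two-parameter model with offset), no IRLS involved.
gridSearchPoisson <- function(y, x, logT) {
  ll <- function(b0, b1) sum(dpois(y, exp(b0 + b1 * x + logT), log = TRUE))
  ctr <- c(0, 0)
  width <- 4
  for (round in 1:5) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 81)
    b1s <- seq(ctr[2] - width, ctr[2] + width, length.out = 81)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    ctr <- c(b0s[best[1]], b1s[best[2]])
    width <- width * 2 / 80 * 2      # zoom to +/- 2 grid steps
  }
  ctr
}

# EMA record table built by hand: `completed` is a logical matrix
# subjects x 70 (day-major, 5 slots per day); counts fill TR-IM slots.
handEma <- function(completed, counts = NULL) {
  n <- nrow(completed)
  grid <- expand.grid(slot = 1:5, day = 1:14)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    df <- data.frame(subject_id = sprintf("S%03d", i),
                     day = grid$day, slot = grid$slot,
                     completed = completed[i, ])
    df$trim_count <- NA_integer_
    sel <- df$completed & df$slot %in% 2:4
    if (!is.null(counts)) df$trim_count[sel] <- counts[[i]]
    else df$trim_count[sel] <- 0L
    df
  }))
  rownames(out) <- NULL
  out
}
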