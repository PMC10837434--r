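#' Seed-voxel association matrix
#'
#' Row s, column v holds the across-subject association between seed s mean
#' density and voxel v density. Pearson correlation is the default (the
#' convention of the PLS toolboxes this analysis family uses); a plain
#' covariance option is available. Voxels (or seeds) with zero variance have
#' an undefined correlation: their associations are set to 0 and flagged.
#'
#' @param cohort a [CohortMatrix-class] (unsmoothed by convention).
#' @param seeds numeric matrix, subjects x 2 (anterior, posterior mean
#'   densities), rows aligned with the cohort matrix.
#' @param method `"correlation"` (default) or `"covariance"`.
#' @return 2 x voxels matrix with attribute `"flagged"` (logical per
#'   voxel).
#' @export
seedVoxelAssociation <- function(cohort, seeds,
                                 method = c("correlation", "covariance")) {
  method <- match.arg(method)
  X <- densityMatrix(cohort)
  seeds <- as.matrix(seeds)
  n <- nrow(X)
  if (nrow(seeds) != n) stop("seed rows must align with cohort rows")
  if (n < 3L) stop("need at least 3 subjects")
  if (ncol(seeds) != 2L) stop("exactly two seed columns expected")
  assocCore(X, seeds, method)
}

# shared by the resampling loops: operates on raw matrices
assocCore <- function(X, seeds, method) {
  n <- nrow(X)
  if (method == "correlation") {
    zx <- standardizeColumns(X)
    zs <- standardizeColumns(seeds)
    if (any(zs$flagged)) stop("seed column has zero variance")
    A <- crossprod(zs$z, zx$z) / (n - 1)
    flagged <- zx$flagged
  } else {
    cx <- centerColumns(X)
    cs <- centerColumns(seeds)
    A <- crossprod(cs, cx) / (n - 1)
    flagged <- rep(FALSE, ncol(X))
  }
  A[, flagged] <- 0
  rownames(A) <- c("ahpc", "phpc")
  attr(A, "flagged") <- flagged
  A
}

#' Non-rotated PLS: project the association matrix onto an a priori contrast
#'
#' Instead of a singular-value decomposition, the latent variable is defined
#' by a contrast over the seeds (e.g. `c(1, -1)` for anterior vs posterior),
#' normalized internally to unit length. Saliences are the contrast-weighted
#' combination of the seed-voxel associations; the singular value is their
#' Euclidean norm. Positive saliences mark voxels covarying with the
#' positively weighted seed.
#'
#' @param assoc 2 x voxels association matrix.
#' @param contrast numeric length 2, nonzero.
#' @return list with `saliences`, `singularValue`, and the normalized
#'   `contrast`.
#' @export
nonrotatedPLS <- function(assoc, contrast = c(1, -1)) {
  if (length(contrast) != 2L || sum(contrast^2) == 0)
    stop("contrast must be a nonzero vector of length 2")
  u <- contrast / sqrt(sum(contrast^2))
  sal <- as.numeric(u %*% assoc)
  list(saliences = sal, singularValue = sqrt(sum(sal^2)), contrast = u)
}

#' Permutation test for the latent variable
#'
#' Subject rows of the seed table are permuted (resampling without
#' replacement) relative to the voxel data `n_perm` times; the p-value is
#' the plain proportion of permuted singular values at least as large as the
#' observed one (the convention of the referenced PLS toolboxes; the
#' `(count + 1) / (n_perm + 1)` variant is available via `convention`).
#'
#' @inheritParams seedVoxelAssociation
#' @param contrast a priori seed contrast.
#' @param n_perm number of permutations (>= 1); 1000 in the canonical
#'   analysis.
#' @param rng_seed integer seed (required; no global RNG state is used).
#' @param convention `"proportion"` (default) or `"add_one"`.
#' @return list with `permP`, `observed` singular value and the vector of
#'   `permuted` singular values.
#' @export
permutationTest <- function(cohort, seeds, contrast = c(1, -1),
                            n_perm = 1000L, rng_seed,
                            method = c("correlation", "covariance"),
                            convention = c("proportion", "add_one")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  X <- densityMatrix(cohort)
  seeds <- as.matrix(seeds)
  n <- nrow(X)
  obs <- nonrotatedPLS(assocCore(X, seeds, method), contrast)$singularValue

  # voxel block standardized once; only the seed block is permuted
  zx <- if (method == "correlation") standardizeColumns(X)$z
        else centerColumns(X)
  u <- contrast / sqrt(sum(contrast^2))
  svOne <- function(sd2) {
    A <- crossprod(sd2, zx) / (n - 1)
    sqrt(sum(as.numeric(u %*% A)^2))
  }
  perm <- withSeed(rng_seed, function() {
    vapply(seq_len(n_perm), function(b) {
      sp <- seeds[sample.int(n), , drop = FALSE]
      sd2 <- if (method == "correlation") standardizeColumns(sp)$z
             else centerColumns(sp)
      svOne(sd2)
    }, numeric(1))
  })
  p <- if (convention == "proportion") mean(perm >= obs)
       else (sum(perm >= obs) + 1) / (n_perm + 1)
  list(permP = p, observed = obs, permuted = perm)
}

#' Bootstrap standard errors and bootstrap ratios for voxel saliences
#'
#' Subjects are resampled with replacement `n_boot` times; saliences are
#' recomputed per replicate with the fixed a priori contrast (no
#' re-standardization or sign-flip correction is needed because the contrast
#' is not data-driven). The bootstrap SE is the across-replicate standard
#' deviation of each voxel's salience, and the bootstrap ratio (BSR) is the
#' original salience divided by its SE. Voxels with zero bootstrap SE get an
#' `NA` ratio and are flagged, never reported as reliable.
#'
#' @inheritParams permutationTest
#' @param n_boot number of bootstrap replicates (>= 2); 1000 in the
#'   canonical analysis.
#' @return list with `bootSE`, `bsr`, `saliences` (observed), and
#'   `flagged` (zero-SE voxels).
#' @export
bootstrapBSR <- function(cohort, seeds, contrast = c(1, -1),
                         n_boot = 1000L, rng_seed,
                         method = c("correlation", "covariance")) {
  method <- match.arg(method)
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) stop("n_boot must be >= 2")
  X <- densityMatrix(cohort)
  seeds <- as.matrix(seeds)
  n <- nrow(X)
  V <- ncol(X)
  u <- contrast / sqrt(sum(contrast^2))
  sal0 <- as.numeric(u %*% assocCore(X, seeds, method))

  acc <- numeric(V)
  acc2 <- numeric(V)
  withSeed(rng_seed, function() {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      sb <- seeds[idx, , drop = FALSE]
      if (method == "correlation") {
        zx <- standardizeColumns(Xb)
        zs <- standardizeColumns(sb)
        if (any(zs$flagged)) { # degenerate resample: seed constant
          next
        }
        A <- crossprod(zs$z, zx$z) / (n - 1)
        A[, zx$flagged] <- 0
      } else {
        A <- crossprod(centerColumns(sb), centerColumns(Xb)) / (n - 1)
      }
      sal <- as.numeric(u %*% A)
      acc <<- acc + sal
      acc2 <<- acc2 + sal * sal
    }
  })
  se <- sqrt(pmax(0, (acc2 - acc^2 / n_boot) / (n_boot - 1)))
  flagged <- se <= 0
  bsr <- sal0 / se
  bsr[flagged] <- NA_real_
  list(bootSE = se, bsr = bsr, saliences = sal0, flagged = flagged)
}

#' Per-subject brain scores
#'
#' The brain score expresses how strongly a subject shows the covariance
#' pattern: the dot product of the subject's (smoothed) GM voxel densities
#' with the latent variable's voxel saliences.
#'
#' @param cohort a smoothed [CohortMatrix-class].
#' @param saliences numeric vector, one weight per cohort-matrix voxel.
#' @return numeric, one score per subject.
#' @export
scoreSubjects <- function(cohort, saliences) {
  X <- densityMatrix(cohort)
  if (ncol(X) != length(saliences))
    stop("voxel count mismatch between cohort matrix and saliences")
  if (!isSmoothed(cohort))
    warning("brain scores are conventionally computed on smoothed images")
  as.numeric(X %*% saliences)
}

#' Full seed-based non-rotated PLS analysis
#'
#' Runs the association matrix, contrast projection, permutation test,
#' bootstrap, and brain scores in one call, returning a
#' [LatentVariable-class].
#'
#' @inheritParams permutationTest
#' @param n_boot bootstrap replicates.
#' @param smoothed_cohort optional smoothed [CohortMatrix-class] (same
#'   voxels) for the brain scores; when omitted, scores are computed on
#'   `cohort`.
#' @return A [LatentVariable-class].
#' @export
seedPLS <- function(cohort, seeds, contrast = c(1, -1),
                    n_perm = 1000L, n_boot = 1000L, rng_seed,
                    method = c("correlation", "covariance"),
                    smoothed_cohort = NULL) {
  method <- match.arg(method)
  A <- seedVoxelAssociation(cohort, seeds, method)
  lv <- nonrotatedPLS(A, contrast)
  pt <- permutationTest(cohort, seeds, contrast, n_perm,
                        rng_seed = rng_seed, method = method)
  bt <- bootstrapBSR(cohort, seeds, contrast, n_boot,
                     rng_seed = rng_seed + 1L, method = method)
  scoreSrc <- if (is.null(smoothed_cohort)) cohort else smoothed_cohort
  scores <- suppressWarnings(scoreSubjects(scoreSrc, lv$saliences))
  new("LatentVariable", contrast = lv$contrast, saliences = lv$saliences,
      singularValue = lv$singularValue, permP = pt$permP,
      bootSE = bt$bootSE, bsr = bt$bsr, brainScores = scores,
      nPerm = as.integer(n_perm), nBoot = as.integer(n_boot),
      seed = as.integer(rng_seed),
      flaggedVoxels = attr(A, "flagged") | bt$flagged)
}

#' @rdname LatentVariable-class
#' @param x a `LatentVariable`.
#' @export
setMethod("saliences", "LatentVariable", function(x) x@saliences)

#' @rdname LatentVariable-class
#' @export
setMethod("singularValue", "LatentVariable", function(x) x@singularValue)

#' @rdname LatentVariable-class
#' @export
setMethod("permP", "LatentVariable", function(x) x@permP)

#' @rdname LatentVariable-class
#' @export
setMethod("bootstrapRatios", "LatentVariable", function(x) x@bsr)

#' @rdname LatentVariable-class
#' @export
setMethod("brainScores", "LatentVariable", function(x) x@brainScores)

setMethod("show", "LatentVariable", function(object) {
  cat(sprintf(
    "LatentVariable: contrast (%.3f, %.3f), singular value %.4g, perm p %s\n",
    object@contrast[1], object@contrast[2], object@singularValue,
    format(object@permP)))
  if (length(object@bsr))
    cat(sprintf("  %d voxels; |BSR| >= 3.3 at %d\n", length(object@bsr),
                sum(abs(object@bsr) >= 3.3, na.rm = TRUE)))
})

#' Map a per-voxel statistic back onto the grid
#'
#' @param cm the [CohortMatrix-class] whose voxel order defines the values.
#' @param values numeric, one per cohort voxel.
#' @param fill value for out-of-mask voxels.
#' @return A [VoxelGrid-class].
#' @export
statMap <- function(cm, values, fill = 0) {
  md <- S4Vectors::metadata(cm)
  a <- array(fill, md$gridDim)
  a[SummarizedExperiment::rowData(cm)$linear] <- values
  VoxelGrid(a, md$affine)
}

#' Extract suprathreshold clusters from a bootstrap-ratio map
#'
#' Connected components of `bsr >= threshold` and, separately, of
#' `bsr <= -threshold`; components smaller than `min_size` voxels are
#' dropped (only clusters of at least 100 voxels are reported in the
#' canonical analysis). Each cluster's peak is its voxel of maximal
#' absolute BSR, reported in mm.
#'
#' @param bsrGrid a [VoxelGrid-class] of bootstrap ratios (NA treated as
#'   subthreshold).
#' @param threshold positive BSR cutoff; default 3.3 (about two-tailed
#'   p = 0.001).
#' @param min_size minimum cluster extent in voxels; default 100.
#' @param connectivity 6, 18 or 26 (default) neighbour connectivity.
#' @return data.frame: `sign`, `peak_x`, `peak_y`, `peak_z`, `size_voxels`,
#'   `peak_bsr`, ordered by decreasing |peak BSR| within sign. Empty
#'   data.frame when nothing survives.
#' @export
extractClusters <- function(bsrGrid, threshold = 3.3, min_size = 100L,
                            connectivity = 26L) {
  if (!isScalar(threshold) || threshold <= 0) stop("threshold must be > 0")
  a <- gridData(bsrGrid)
  a[is.na(a)] <- 0
  aff <- gridAffine(bsrGrid)
  out <- list()
  for (sgn in c("positive", "negative")) {
    mask <- if (sgn == "positive") a >= threshold else a <= -threshold
    comps <- connectedComponents(mask, connectivity)
    for (comp in comps) {
      if (length(comp) < min_size) next
      peak <- comp[which.max(abs(a[comp]))]
      mm <- voxelToMM(aff, arrayInd(peak, dim(a)))
      out[[length(out) + 1L]] <- data.frame(
        sign = sgn, peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        size_voxels = length(comp), peak_bsr = a[peak],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sign = character(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      size_voxels = integer(0), peak_bsr = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$sign, -abs(res$peak_bsr)), , drop = FALSE]
}

# Connected components of a logical 3-D array; returns a list of linear
# index vectors. Iterative stack-based flood fill.
connectedComponents <- function(mask, connectivity = 26L) {
  off <- neighborOffsets(connectivity)
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  visited <- array(FALSE, d)
  strides <- c(1L, d[1], d[1] * d[2])
  offLin <- as.integer(off %*% strides)
  comps <- list()
  for (start in idx) {
    if (visited[start]) next
    stack <- start
    visited[start] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        ni <- ci + off[r, ]
        if (any(ni < 1L) || any(ni > d)) next
        nl <- cur + offLin[r]
        if (mask[nl] && !visited[nl]) {
          visited[nl] <- TRUE
          stack <- c(stack, nl)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}
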