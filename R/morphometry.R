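#' Mean gray-matter density within a mask
#'
#' @param img a [GMImage-class] (or any [VoxelGrid-class]).
#' @param mask binary [VoxelGrid-class], nonempty, same geometry.
#' @return arithmetic mean of in-mask densities.
#' @export
meanDensity <- function(img, mask) {
  if (!sameGeometry(img, mask)) stop("image and mask geometry differ")
  idx <- gridData(mask) > 0
  if (!any(idx)) stop("mask is empty")
  mean(gridData(img)[idx])
}

#' Subregion volume from mean density and voxel count
#'
#' Volume is the mean GM density within each hemisphere mask multiplied by
#' that mask's voxel count, summed over left and right hemispheres —
#' algebraically the sum of in-mask densities. Units are density-weighted
#' voxels by default; `mm3 = TRUE` multiplies by the voxel volume.
#'
#' @param img a [GMImage-class].
#' @param left,right nonempty binary hemisphere masks.
#' @param mm3 report in density-weighted mm^3 instead of voxel units.
#' @return scalar volume.
#' @export
subregionVolume <- function(img, left, right, mm3 = FALSE) {
  vols <- vapply(list(left, right), function(m) {
    idx <- gridData(m) > 0
    if (!any(idx)) stop("empty hemisphere mask")
    meanDensity(img, m) * sum(idx)
  }, numeric(1))
  out <- sum(vols)
  if (mm3) out <- out * prod(voxelSizes(gridAffine(img)))
  out
}

#' Split a bilateral mask into hemispheres by the sign of x
#'
#' @param mask binary [VoxelGrid-class].
#' @return list with binary masks `left` (x < 0) and `right` (x > 0).
#' @export
splitHemispheres <- function(mask) {
  x <- axisCoordinateArray(mask, 1L)
  m <- gridData(mask) > 0
  aff <- gridAffine(mask)
  list(left = VoxelGrid((m & x < 0) + 0, aff),
       right = VoxelGrid((m & x > 0) + 0, aff))
}

#' Cohort analysis mask from the average GM image
#'
#' A voxel enters the analysis mask when the across-subject mean density
#' strictly exceeds `threshold` (default 0.1, a conventional gray-matter
#' cutoff).
#'
#' @param imgs list of >= 2 [GMImage-class] sharing geometry.
#' @param threshold mean-density cutoff.
#' @return binary [VoxelGrid-class].
#' @export
buildAnalysisMask <- function(imgs, threshold = 0.1) {
  if (length(imgs) < 2L) stop("need at least 2 images")
  ref <- imgs[[1]]
  acc <- array(0, dim(gridData(ref)))
  for (im in imgs) {
    if (!sameGeometry(ref, im)) stop("images differ in shape or affine")
    acc <- acc + gridData(im)
  }
  acc <- acc / length(imgs)
  keep <- acc > threshold
  if (!any(keep))
    stop("analysis mask is empty at threshold ", threshold,
         " (global max mean density is ", signif(max(acc), 4), ")")
  VoxelGrid(keep + 0, gridAffine(ref))
}

# 1-D discretely sampled Gaussian kernel, normalized to unit sum.
gaussianKernel1d <- function(sigma_vox) {
  h <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-h):h)^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# Dense 1-D smoothing operator with mirrored (half-sample reflect) boundary.
# Reflection folding makes the operator symmetric, so both row and column
# sums are 1 and total mass is conserved.
smoothingMatrix <- function(n, sigma_vox) {
  w <- gaussianKernel1d(sigma_vox)
  h <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -h:h) {
      j <- i + o
      while (j < 1L || j > n) {
        if (j < 1L) j <- 1L - j
        if (j > n) j <- 2L * n + 1L - j
      }
      K[i, j] <- K[i, j] + w[o + h + 1L]
    }
  }
  K
}

#' Isotropic Gaussian smoothing of a GM image
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 log 2))` mm per axis,
#' converted to voxels by the affine's voxel sizes; boundaries are handled
#' by mirroring, which conserves total mass. The output is flagged smoothed.
#'
#' @param img a [GMImage-class].
#' @param fwhm_mm full width at half maximum in mm (> 0); default 8, the
#'   standard VBM choice.
#' @return smoothed [GMImage-class].
#' @export
smoothImage <- function(img, fwhm_mm = 8) {
  if (!isScalar(fwhm_mm) || fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  sigMM <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxelSizes(gridAffine(img))
  a <- gridData(img)
  d <- dim(a)
  K1 <- smoothingMatrix(d[1], sigMM / vs[1])
  a <- array(K1 %*% matrix(a, d[1]), d)
  K2 <- smoothingMatrix(d[2], sigMM / vs[2])
  p <- aperm(a, c(2, 1, 3))
  p <- array(K2 %*% matrix(p, d[2]), c(d[2], d[1], d[3]))
  a <- aperm(p, c(2, 1, 3))
  K3 <- smoothingMatrix(d[3], sigMM / vs[3])
  a <- array(matrix(a, d[1] * d[2], d[3]) %*% t(K3), d)
  a[a < 0] <- 0                       # numerical negatives only
  new("GMImage", data = a, affine = gridAffine(img),
      subjectID = if (is(img, "GMImage")) img@subjectID else "",
      smoothed = TRUE)
}

#' Assemble a cohort matrix from images and an analysis mask
#'
#' Stacks each subject's in-mask voxel densities into a
#' [CohortMatrix-class]; column order is the mask's linear-index order, and
#' row metadata records each voxel's grid and mm coordinates so images can
#' be reassembled exactly ([cohortImages()]).
#'
#' @param imgs list of [GMImage-class], one per subject, shared geometry.
#' @param mask binary analysis [VoxelGrid-class].
#' @return A [CohortMatrix-class].
#' @export
buildCohortMatrix <- function(imgs, mask) {
  if (!length(imgs)) stop("no images")
  ref <- imgs[[1]]
  if (!sameGeometry(ref, mask)) stop("mask geometry differs from images")
  idx <- which(gridData(mask) > 0)
  if (!length(idx)) stop("analysis mask is empty")
  ijk <- arrayInd(idx, dim(gridData(mask)))
  mm <- voxelToMM(gridAffine(mask), ijk)
  smoothed <- vapply(imgs, function(im) isTRUE(im@smoothed), logical(1))
  if (!all(smoothed == smoothed[1]))
    stop("images mix smoothed and unsmoothed maps")
  ids <- vapply(imgs, function(im) im@subjectID, character(1))
  assay <- vapply(imgs, function(im) {
    if (!sameGeometry(ref, im)) stop("images differ in shape or affine")
    gridData(im)[idx]
  }, numeric(length(idx)))
  rd <- S4Vectors::DataFrame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                             x = mm[, 1], y = mm[, 2], z = mm[, 3],
                             linear = idx)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(density = assay), rowData = rd,
    colData = S4Vectors::DataFrame(subject_id = ids, row.names = ids),
    metadata = list(affine = gridAffine(mask),
                    gridDim = dim(gridData(mask)),
                    smoothed = smoothed[1]))
  new("CohortMatrix", se)
}

#' @rdname CohortMatrix-class
#' @param x a `CohortMatrix`.
#' @export
setMethod("densityMatrix", "CohortMatrix", function(x)
  t(SummarizedExperiment::assay(x, "density")))

#' @rdname CohortMatrix-class
#' @export
setMethod("voxelCoords", "CohortMatrix", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname CohortMatrix-class
#' @export
setMethod("isSmoothed", "CohortMatrix", function(x)
  isTRUE(S4Vectors::metadata(x)$smoothed))

#' @rdname CohortMatrix-class
#' @export
setMethod("subjectIDs", "CohortMatrix", function(x)
  SummarizedExperiment::colData(x)$subject_id)

#' Reassemble per-subject grids from a cohort matrix
#'
#' Inverse of [buildCohortMatrix()] on the masked voxels: out-of-mask voxels
#' are zero-filled.
#'
#' @param cm a [CohortMatrix-class].
#' @return list of [GMImage-class].
#' @export
cohortImages <- function(cm) {
  md <- S4Vectors::metadata(cm)
  lin <- SummarizedExperiment::rowData(cm)$linear
  ids <- subjectIDs(cm)
  M <- SummarizedExperiment::assay(cm, "density")
  lapply(seq_along(ids), function(s) {
    a <- array(0, md$gridDim)
    a[lin] <- M[, s]
    new("GMImage", data = a, affine = md$affine, subjectID = ids[s],
        smoothed = isTRUE(md$smoothed))
  })
}

#' Per-subject seed mean densities
#'
#' Mean unsmoothed GM density within the bilateral anterior and posterior
#' seed templates, for each subject; the two seed columns feed the
#' seed-voxel association matrix.
#'
#' @param imgs list of unsmoothed [GMImage-class].
#' @param anterior,posterior bilateral binary seed masks.
#' @return data.frame: `subject_id`, `ahpc`, `phpc`.
#' @export
seedDensities <- function(imgs, anterior, posterior) {
  data.frame(
    subject_id = vapply(imgs, function(im) im@subjectID, character(1)),
    ahpc = vapply(imgs, meanDensity, numeric(1), mask = anterior),
    phpc = vapply(imgs, meanDensity, numeric(1), mask = posterior),
    stringsAsFactors = FALSE)
}

#' Per-subject subregion volume table
#'
#' @param imgs list of unsmoothed [GMImage-class].
#' @param anterior,posterior bilateral binary subregion masks (split into
#'   hemispheres internally by the sign of x).
#' @param mm3 report volumes in mm^3.
#' @return data.frame: `subject_id`, `aHPC_volume`, `pHPC_volume`,
#'   `aHPC_mean_density`, `pHPC_mean_density`.
#' @export
volumeTable <- function(imgs, anterior, posterior, mm3 = FALSE) {
  antH <- splitHemispheres(anterior)
  postH <- splitHemispheres(posterior)
  data.frame(
    subject_id = vapply(imgs, function(im) im@subjectID, character(1)),
    aHPC_volume = vapply(imgs, subregionVolume, numeric(1),
                         left = antH$left, right = antH$right, mm3 = mm3),
    pHPC_volume = vapply(imgs, subregionVolume, numeric(1),
                         left = postH$left, right = postH$right, mm3 = mm3),
    aHPC_mean_density = vapply(imgs, meanDensity, numeric(1),
                               mask = anterior),
    pHPC_mean_density = vapply(imgs, meanDensity, numeric(1),
                               mask = posterior),
    stringsAsFactors = FALSE)
}
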