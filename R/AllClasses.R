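#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rnorm rbinom rpois runif sd cor cor.test glm poisson
#'   glm.control coef dpois ks.test logLik offset pnorm qnorm quantile
#'   residuals setNames
#' @importFrom utils head
NULL

#' VoxelGrid: a 3-D lattice of values with a voxel-to-mm affine
#'
#' The backbone container for gray-matter density maps, binary masks, label
#' maps, and statistical (salience / bootstrap-ratio) maps. The affine maps
#' 0-based voxel indices `(i-1, j-1, k-1, 1)` to RAS+ millimetre coordinates,
#' following the NIfTI-1 convention.
#'
#' @slot data 3-D numeric array of voxel values.
#' @slot affine 4x4 numeric matrix; last row `(0, 0, 0, 1)`.
#'
#' @seealso [VoxelGrid()], [readVoxelGrid()], [writeVoxelGrid()]
#' @export
setClass("VoxelGrid", slots = c(data = "array", affine = "matrix"))

setValidity("VoxelGrid", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else {
    if (!all(is.finite(object@affine)))
      msg <- c(msg, "affine must be finite")
    else if (!isTRUE(all.equal(object@affine[4L, ], c(0, 0, 0, 1))))
      msg <- c(msg, "last affine row must be (0, 0, 0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' GMImage: a per-subject modulated gray-matter density map
#'
#' A [VoxelGrid-class] whose values are non-negative modulated gray-matter
#' densities, tagged with a subject identifier and a smoothing flag. Seed
#' densities and the voxelwise covariance matrix are computed from unsmoothed
#' images; brain scores use smoothed images.
#'
#' @slot subjectID single character identifier.
#' @slot smoothed logical; `TRUE` after [smoothImage()].
#' @export
setClass("GMImage", contains = "VoxelGrid",
         slots = c(subjectID = "character", smoothed = "logical"))

setValidity("GMImage", function(object) {
  msg <- character(0)
  if (length(object@subjectID) != 1L)
    msg <- c(msg, "subjectID must be length 1")
  if (length(object@smoothed) != 1L || is.na(object@smoothed))
    msg <- c(msg, "smoothed must be TRUE or FALSE")
  v <- object@data
  if (!all(is.finite(v)))
    msg <- c(msg, "densities must be finite")
  else if (min(v) < 0)
    msg <- c(msg, "densities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ProbabilisticTemplate: voxelwise subject-coverage fractions
#'
#' Built by merging per-subject binary subregion masks: each voxel's value is
#' the fraction of subjects whose mask contains it, an exact rational k/n.
#'
#' @slot grid a [VoxelGrid-class] with values in `[0, 1]`.
#' @slot nSubjects number of masks merged.
#' @slot regionName identifier, e.g. `"aHPC_left"`.
#' @seealso [buildProbabilisticTemplate()], [thresholdTemplate()]
#' @export
setClass("ProbabilisticTemplate",
         slots = c(grid = "VoxelGrid", nSubjects = "integer",
                   regionName = "character"))

setValidity("ProbabilisticTemplate", function(object) {
  msg <- character(0)
  n <- object@nSubjects
  if (length(n) != 1L || is.na(n) || n < 1L)
    msg <- c(msg, "nSubjects must be a positive integer")
  v <- object@grid@data
  if (length(msg) == 0L) {
    k <- v * n
    if (max(abs(k - round(k))) > 1e-9 || min(v) < 0 || max(v) > 1)
      msg <- c(msg, "template values must be exact fractions k/nSubjects in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' CohortMatrix: subjects-by-voxels density matrix
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the in-mask voxel densities of a cohort. The assay `"density"` is
#' stored voxels-by-subjects (features in rows, Bioconductor convention);
#' [densityMatrix()] returns the subjects-by-voxels orientation used by the
#' PLS machinery. `rowData` carries each voxel's grid coordinates (`i`, `j`,
#' `k`, 1-based) and mm coordinates (`x`, `y`, `z`); metadata carries the
#' affine and the smoothing flag.
#'
#' @seealso [buildCohortMatrix()], [cohortImages()]
#' @export
setClass("CohortMatrix", contains = "SummarizedExperiment")

#' LatentVariable: a contrast-defined structural covariance pattern
#'
#' Result of seed-based non-rotated PLS: the a priori contrast over the two
#' seeds, per-voxel saliences (weights), the singular value (Euclidean norm
#' of the salience vector), permutation p-value, bootstrap standard errors
#' and bootstrap ratios (BSR), and per-subject brain scores.
#'
#' @slot contrast numeric length 2, normalized to unit length.
#' @slot saliences numeric, one weight per analysis-mask voxel.
#' @slot singularValue non-negative scalar, `sqrt(sum(saliences^2))`.
#' @slot permP permutation p-value (NA if no permutation test was run).
#' @slot bootSE per-voxel bootstrap SE of the salience (NA if not run).
#' @slot bsr per-voxel bootstrap ratio, salience / bootSE; NA where the
#'   bootstrap SE is zero (flagged, never reported as reliable).
#' @slot brainScores per-subject dot product of (smoothed) densities with
#'   the saliences.
#' @slot nPerm,nBoot resampling sizes used.
#' @slot seed RNG seed used for resampling.
#' @slot flaggedVoxels voxels whose association was undefined (zero
#'   variance) and set to 0.
#' @export
setClass("LatentVariable",
         slots = c(contrast = "numeric", saliences = "numeric",
                   singularValue = "numeric", permP = "numeric",
                   bootSE = "numeric", bsr = "numeric",
                   brainScores = "numeric", nPerm = "integer",
                   nBoot = "integer", seed = "integer",
                   flaggedVoxels = "logical"))

setValidity("LatentVariable", function(object) {
  msg <- character(0)
  if (length(object@contrast) != 2L)
    msg <- c(msg, "contrast must have length 2")
  sv <- sqrt(sum(object@saliences^2))
  if (length(object@singularValue) != 1L ||
      abs(object@singularValue - sv) > 1e-8 * max(1, sv))
    msg <- c(msg, "singularValue must equal the Euclidean norm of the saliences")
  if (!is.na(object@permP) && (object@permP < 0 || object@permP > 1))
    msg <- c(msg, "permP must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PoissonFit: an offset Poisson count model with Wald inference
#'
#' Coefficients on the standardized-predictor scale, Wald standard errors,
#' incidence rate ratios (IRR = exp(coefficient)) with 95% confidence
#' intervals `exp(b +/- 1.96 se)`, model and null log-likelihoods, Nagelkerke
#' pseudo-R-squared, and a Pearson dispersion diagnostic.
#'
#' @slot coefficients data.frame with columns term, estimate, se, z, p,
#'   irr, irr_lo, irr_hi.
#' @slot logLik,logLikNull model and intercept+offset-only log-likelihoods.
#' @slot nagelkerke Nagelkerke R-squared in `[0, 1)`.
#' @slot converged IRLS convergence flag.
#' @slot n number of subjects fitted.
#' @slot dispersion Pearson chi-squared / residual df.
#' @slot model short label for the model specification.
#' @export
setClass("PoissonFit",
         slots = c(coefficients = "data.frame", logLik = "numeric",
                   logLikNull = "numeric", nagelkerke = "numeric",
                   converged = "logical", n = "integer",
                   dispersion = "numeric", model = "character"))

#' SynthCohort: a simulated cohort with known planted structure
#'
#' Everything a downstream analysis consumes, plus the ground truth needed
#' to verify recovery: per-subject GM density maps, per-subject subregion
#' label maps, the truth record (latent factors, region memberships, layout),
#' the subject covariate table, and the long-format EMA record table.
#'
#' @slot gmImages list of [GMImage-class], one per subject.
#' @slot subjectMasks list of label [VoxelGrid-class] (codes 0 background,
#'   1 head, 2 body, 3 tail), one per subject.
#' @slot truth list: `f`, `g` (latent factors), `trueScore` (standardized f,
#'   the planted brain-score proxy), `labels` (truth label grid),
#'   `networkMask`, `brainMask`, `layout`.
#' @slot subjects subject covariate data.frame.
#' @slot ema long-format EMA record data.frame.
#' @slot config the generating configuration.
#' @export
setClass("SynthCohort",
         slots = c(gmImages = "list", subjectMasks = "list", truth = "list",
                   subjects = "data.frame", ema = "data.frame",
                   config = "list"))

setValidity("SynthCohort", function(object) {
  msg <- character(0)
  n <- nrow(object@subjects)
  if (length(object@gmImages) != n || length(object@subjectMasks) != n)
    msg <- c(msg, "need one image and one mask per subject")
  if (n > 0L) {
    d <- dim(object@gmImages[[1]]@data)
    a <- object@gmImages[[1]]@affine
    same <- vapply(seq_len(n), function(i) {
      identical(dim(object@gmImages[[i]]@data), d) &&
        identical(dim(object@subjectMasks[[i]]@data), d) &&
        isTRUE(all.equal(object@gmImages[[i]]@affine, a)) &&
        isTRUE(all.equal(object@subjectMasks[[i]]@affine, a))
    }, logical(1))
    if (!all(same)) msg <- c(msg, "all grids must share shape and affine")
  }
  if (length(msg)) msg else TRUE
})
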