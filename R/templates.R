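#' Template-building configuration
#'
#' The probability threshold and the longitudinal-axis cut coordinates used
#' to finalize anterior/posterior hippocampus templates. Voxels are retained
#' when present in at least `prob_threshold` of the sample (inclusive), the
#' posterior template keeps voxel centres at `y <= posterior_cut_mm`, the
#' anterior template keeps `y >= anterior_cut_mm`, and the middle portion of
#' the hippocampus (strictly between the cuts) belongs to neither.
#'
#' @param prob_threshold retention probability in `(0, 1]`; default 0.75.
#' @param posterior_cut_mm posterior cut (default -32 mm).
#' @param anterior_cut_mm anterior cut (default -21 mm).
#' @return list of class `"TemplateConfig"`.
#' @export
templateConfig <- function(prob_threshold = 0.75,
                           posterior_cut_mm = -32,
                           anterior_cut_mm = -21) {
  if (!isScalar(prob_threshold) || prob_threshold <= 0 || prob_threshold > 1)
    stop("prob_threshold must lie in (0, 1]")
  if (!isScalar(posterior_cut_mm) || !isScalar(anterior_cut_mm) ||
      posterior_cut_mm >= anterior_cut_mm)
    stop("posterior_cut_mm must be less than anterior_cut_mm")
  structure(list(prob_threshold = prob_threshold,
                 posterior_cut_mm = posterior_cut_mm,
                 anterior_cut_mm = anterior_cut_mm),
            class = "TemplateConfig")
}

#' Aggregate hippocampal subfield labels into anterior/posterior masks
#'
#' The anterior subregion is the head (code 1); the posterior subregion is
#' body plus tail (codes 2 and 3). The two masks are disjoint by
#' construction.
#'
#' @param labels label [VoxelGrid-class] with codes 0-3.
#' @return list with binary [VoxelGrid-class] elements `anterior` and
#'   `posterior`.
#' @export
aggregateSubfields <- function(labels) {
  lab <- gridData(labels)
  if (!all(unique(as.vector(lab)) %in% 0:3))
    stop("unknown label codes: expected {0, 1, 2, 3}")
  aff <- gridAffine(labels)
  list(anterior = VoxelGrid((lab == 1) + 0, aff),
       posterior = VoxelGrid((lab == 2 | lab == 3) + 0, aff))
}

#' Merge binary masks into a probabilistic template
#'
#' Each voxel's value is the exact fraction of masks containing it
#' (an integer count over `n`), so thresholding decisions are exact rational
#' comparisons.
#'
#' @param masks list of >= 2 binary [VoxelGrid-class] with identical shape
#'   and affine.
#' @param region_name identifier stored on the template.
#' @return A [ProbabilisticTemplate-class].
#' @export
buildProbabilisticTemplate <- function(masks, region_name = "region") {
  if (length(masks) < 2L) stop("need at least 2 masks")
  ref <- masks[[1]]
  for (m in masks[-1])
    if (!sameGeometry(ref, m)) stop("masks differ in shape or affine")
  n <- length(masks)
  acc <- array(0, dim(gridData(ref)))
  for (m in masks) acc <- acc + (gridData(m) > 0)
  new("ProbabilisticTemplate",
      grid = VoxelGrid(acc / n, gridAffine(ref)),
      nSubjects = as.integer(n), regionName = region_name)
}

#' @rdname ProbabilisticTemplate-class
#' @param x a `ProbabilisticTemplate`.
#' @export
setMethod("regionName", "ProbabilisticTemplate", function(x) x@regionName)

#' @rdname ProbabilisticTemplate-class
#' @export
setMethod("nSubjects", "ProbabilisticTemplate", function(x) x@nSubjects)

#' @rdname ProbabilisticTemplate-class
#' @export
setMethod("gridData", "ProbabilisticTemplate", function(x) x@grid@data)

#' @rdname ProbabilisticTemplate-class
#' @export
setMethod("gridAffine", "ProbabilisticTemplate", function(x) x@grid@affine)

setMethod("show", "ProbabilisticTemplate", function(object) {
  cat(sprintf("ProbabilisticTemplate '%s': %d subjects, %d voxels ever present\n",
              object@regionName, object@nSubjects,
              sum(object@grid@data > 0)))
})

#' Threshold a probabilistic template
#'
#' A voxel is retained iff its coverage fraction is at least `p`
#' ("present at least in" is inclusive). An empty result is returned with a
#' warning, not an error.
#'
#' @param template a [ProbabilisticTemplate-class].
#' @param p retention probability in `(0, 1]`.
#' @return binary [VoxelGrid-class].
#' @export
thresholdTemplate <- function(template, p) {
  if (!isScalar(p) || p <= 0 || p > 1) stop("p must lie in (0, 1]")
  v <- (gridData(template) >= p) + 0
  if (sum(v) == 0)
    warning("thresholded template is empty at p = ", p)
  VoxelGrid(v, gridAffine(template))
}

#' Apply longitudinal-axis cuts to anterior/posterior masks
#'
#' Membership is decided by the voxel-centre y coordinate (mm): the
#' posterior mask keeps voxels with `y <= posterior_cut_mm`, the anterior
#' mask keeps `y >= anterior_cut_mm` (both inclusive, so the printed cut
#' coordinates are themselves retained), and no retained voxel falls
#' strictly between the cuts.
#'
#' @param anterior,posterior binary [VoxelGrid-class] masks.
#' @param config a [templateConfig()].
#' @return list with cut `anterior` and `posterior` masks.
#' @export
applyAxisCuts <- function(anterior, posterior, config = templateConfig()) {
  stopifnot(inherits(config, "TemplateConfig"))
  for (m in list(anterior, posterior)) {
    yrow <- gridAffine(m)[2, 1:3]
    if (all(abs(yrow) < 1e-12))
      stop("affine has no resolvable y (anterior-posterior) axis")
  }
  yA <- axisCoordinateArray(anterior, 2L)
  yP <- axisCoordinateArray(posterior, 2L)
  antOut <- (gridData(anterior) > 0 & yA >= config$anterior_cut_mm) + 0
  postOut <- (gridData(posterior) > 0 & yP <= config$posterior_cut_mm) + 0
  list(anterior = VoxelGrid(antOut, gridAffine(anterior)),
       posterior = VoxelGrid(postOut, gridAffine(posterior)))
}

#' Write a template with its metadata sidecar
#'
#' Writes the probabilistic template as NIfTI plus a JSON sidecar recording
#' the number of subjects, threshold and cut coordinates.
#'
#' @param template a [ProbabilisticTemplate-class].
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   `.json`.
#' @param config a [templateConfig()].
#' @return `path`, invisibly.
#' @export
writeTemplate <- function(template, path, config = templateConfig()) {
  writeVoxelGrid(template@grid, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(region = template@regionName,
                            n_subjects = template@nSubjects,
                            prob_threshold = config$prob_threshold,
                            posterior_cut_mm = config$posterior_cut_mm,
                            anterior_cut_mm = config$anterior_cut_mm),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
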