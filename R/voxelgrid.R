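#' Construct a VoxelGrid
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm (RAS+),
#'   NIfTI-1 convention. Defaults to an identity spacing of 1 mm.
#' @return A [VoxelGrid-class].
#' @examples
#' g <- VoxelGrid(array(0, c(8, 8, 8)), affineFromSpacing(2, c(8, 8, 8)))
#' dim(g)
#' @export
VoxelGrid <- function(data, affine = diag(4)) {
  new("VoxelGrid", data = data, affine = affine)
}

#' Build a centred axis-aligned RAS+ affine
#'
#' Convenience constructor: isotropic spacing with the grid centred on the
#' origin in x and z, and the y origin chosen by `yOffset` (voxel centre of
#' the first slab).
#'
#' @param spacing voxel size in mm.
#' @param shape grid dimensions.
#' @param yOffset y coordinate (mm) of the first voxel centre; default
#'   centres y as well.
#' @export
affineFromSpacing <- function(spacing, shape, yOffset = NULL) {
  A <- diag(c(spacing, spacing, spacing, 1))
  A[1, 4] <- -spacing * (shape[1] - 1) / 2
  A[2, 4] <- if (is.null(yOffset)) -spacing * (shape[2] - 1) / 2 else yOffset
  A[3, 4] <- -spacing * (shape[3] - 1) / 2
  A
}

#' @rdname VoxelGrid
#' @export
setMethod("gridData", "VoxelGrid", function(x) x@data)

#' @rdname VoxelGrid
#' @export
setMethod("gridAffine", "VoxelGrid", function(x) x@affine)

#' @rdname VoxelGrid
#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@data))

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm\n",
              class(object), d[1], d[2], d[3],
              paste(signif(voxelSizes(object@affine), 3), collapse = " x ")))
})

setMethod("show", "GMImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("GMImage '%s': %d x %d x %d voxels (%s)\n",
              object@subjectID, d[1], d[2], d[3],
              if (object@smoothed) "smoothed" else "unsmoothed"))
})

#' Voxel sizes implied by an affine
#'
#' @param affine 4x4 voxel-to-mm matrix.
#' @return numeric length 3, mm per voxel along each grid axis.
#' @export
voxelSizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# mm coordinate of every voxel centre along one world axis (1 = x, 2 = y,
# 3 = z), as an array matching the grid. Works for any affine.
axisCoordinateArray <- function(grid, axis) {
  a <- gridData(grid)
  r <- gridAffine(grid)[axis, ]
  r[1] * (slice.index(a, 1) - 1) + r[2] * (slice.index(a, 2) - 1) +
    r[3] * (slice.index(a, 3) - 1) + r[4]
}

#' Convert 1-based voxel indices to mm coordinates
#'
#' @param affine 4x4 voxel-to-mm matrix (0-based index convention).
#' @param ijk matrix (or vector) of 1-based voxel indices.
#' @return matrix of x, y, z mm coordinates.
#' @export
voxelToMM <- function(affine, ijk) {
  ijk <- rbind(ijk)
  h <- cbind(ijk - 1, 1)
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# TRUE when two grids share shape and affine (to tolerance).
sameGeometry <- function(a, b, tol = 1e-6) {
  identical(dim(a@data), dim(b@data)) &&
    max(abs(a@affine - b@affine)) <= tol
}

#' Read / write a VoxelGrid as NIfTI-1
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry the affine (sform and qform, aligned code) and voxel sizes.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param grid a [VoxelGrid-class].
#' @return `readVoxelGrid` returns a [VoxelGrid-class]; `writeVoxelGrid`
#'   returns `path` invisibly.
#' @export
readVoxelGrid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  VoxelGrid(array(as.numeric(img), dim = dim(img)), aff)
}

#' @rdname readVoxelGrid
#' @export
writeVoxelGrid <- function(grid, path) {
  img <- RNifti::asNifti(gridData(grid))
  RNifti::pixdim(img) <- voxelSizes(gridAffine(grid))
  aff <- structure(gridAffine(grid), code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}
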