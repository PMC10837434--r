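#' @rdname VoxelGrid
#' @param x,object an object.
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' @rdname VoxelGrid
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))

#' @rdname ProbabilisticTemplate-class
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))

#' @rdname ProbabilisticTemplate-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("densityMatrix", function(x) standardGeneric("densityMatrix"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("isSmoothed", function(x) standardGeneric("isSmoothed"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))

#' @rdname LatentVariable-class
#' @export
setGeneric("saliences", function(x) standardGeneric("saliences"))

#' @rdname LatentVariable-class
#' @export
setGeneric("singularValue", function(x) standardGeneric("singularValue"))

#' @rdname LatentVariable-class
#' @export
setGeneric("permP", function(x) standardGeneric("permP"))

#' @rdname LatentVariable-class
#' @export
setGeneric("bootstrapRatios", function(x) standardGeneric("bootstrapRatios"))

#' @rdname LatentVariable-class
#' @export
setGeneric("brainScores", function(x) standardGeneric("brainScores"))

#' @rdname PoissonFit-class
#' @export
setGeneric("irrTable", function(x) standardGeneric("irrTable"))

#' @rdname PoissonFit-class
#' @export
setGeneric("nagelkerkeR2", function(x, ...) standardGeneric("nagelkerkeR2"))
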