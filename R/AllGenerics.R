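#' Accessors for depthIEM objects
#'
#' Small accessor generics exposing the slots of the package's S4 classes:
#' grid locations, pixel coordinates, basis matrices, trial responses and
#' metadata, reconstruction curves, fitted curve parameters and bootstrap
#' values.
#'
#' @param object an object of the documented class.
#' @param ... unused.
#' @return the requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridLocations", function(object, ...) standardGeneric("gridLocations"))

#' @rdname accessors
#' @export
setMethod("gridLocations", "StimulusGrid", function(object, ...) object@locations)

#' @rdname accessors
#' @export
setGeneric("pixelCoords", function(object, ...) standardGeneric("pixelCoords"))

#' @rdname accessors
#' @export
setMethod("pixelCoords", "PixelGrid", function(object, ...) object@coords)

#' @rdname accessors
#' @export
setMethod("pixelCoords", "SpatialBasis", function(object, ...) object@pixels@coords)

#' @rdname accessors
#' @export
setMethod("pixelCoords", "Reconstruction", function(object, ...) object@pixels@coords)

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(object, ...) standardGeneric("basisMatrix"))

#' @rdname accessors
#' @export
setMethod("basisMatrix", "SpatialBasis", function(object, ...) object@F)

#' @rdname accessors
#' @export
setGeneric("basisCenters", function(object, ...) standardGeneric("basisCenters"))

#' @rdname accessors
#' @export
setMethod("basisCenters", "SpatialBasis", function(object, ...) object@centers)

#' @rdname accessors
#' @export
setGeneric("trialResponses", function(object, ...) standardGeneric("trialResponses"))

#' @rdname accessors
#' @export
setMethod("trialResponses", "TrialExperiment", function(object, ...)
  assay(object, "response"))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(object, ...) standardGeneric("trialInfo"))

#' @rdname accessors
#' @export
setMethod("trialInfo", "TrialExperiment", function(object, ...)
  as.data.frame(colData(object)))

#' @rdname accessors
#' @export
setGeneric("reconCurves", function(object, ...) standardGeneric("reconCurves"))

#' @rdname accessors
#' @export
setMethod("reconCurves", "Reconstruction", function(object, ...) object@curves)

#' @rdname accessors
#' @export
setGeneric("reconInfo", function(object, ...) standardGeneric("reconInfo"))

#' @rdname accessors
#' @export
setMethod("reconInfo", "Reconstruction", function(object, ...) object@info)

#' @rdname accessors
#' @export
setGeneric("voxelWeights", function(object, ...) standardGeneric("voxelWeights"))

#' @param axis for `voxelWeights`, which tuned axis to return (`"x"` or `"z"`).
#' @rdname accessors
#' @export
setMethod("voxelWeights", "VoxelPopulation", function(object, axis = "z", ...) {
  if (!axis %in% names(object@weights))
    stop("no generative weights for axis '", axis, "'")
  object@weights[[axis]]
})

#' @rdname accessors
#' @export
setGeneric("subjectData", function(object, ...) standardGeneric("subjectData"))

#' @param i for `subjectData`, the subject index.
#' @rdname accessors
#' @export
setMethod("subjectData", "SimulatedExperiment", function(object, i, ...)
  object@subjects[[i]])

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(object, ...) standardGeneric("nSubjects"))

#' @rdname accessors
#' @export
setMethod("nSubjects", "SimulatedExperiment", function(object, ...)
  length(object@subjects))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object, ...) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setMethod("fitParams", "CurveFit", function(object, ...)
  c(center = object@center, size = object@size,
    amplitude = object@amplitude, baseline = object@baseline))

#' @rdname accessors
#' @export
setGeneric("fitRmse", function(object, ...) standardGeneric("fitRmse"))

#' @rdname accessors
#' @export
setMethod("fitRmse", "CurveFit", function(object, ...) object@rmse)

#' @rdname accessors
#' @export
setGeneric("bootValues", function(object, ...) standardGeneric("bootValues"))

#' @rdname accessors
#' @export
setMethod("bootValues", "BootstrapDistribution", function(object, ...)
  object@values)

#' @rdname accessors
#' @export
setGeneric("bootCI", function(object, ...) standardGeneric("bootCI"))

#' @rdname accessors
#' @export
setMethod("bootCI", "BootstrapDistribution", function(object, ...)
  rbind(lower = object@ciLower, upper = object@ciUpper))

#' @rdname accessors
#' @export
setGeneric("bootPoint", function(object, ...) standardGeneric("bootPoint"))

#' @rdname accessors
#' @export
setMethod("bootPoint", "BootstrapDistribution", function(object, ...)
  object@point)
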