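#' Viewing geometry of the rendered stereo scene
#'
#' Describes the stereo rendering setup: two eyes placed symmetrically about
#' the midline, fixating a point straight ahead at `fixationDistance` scene
#' units. Disparity and eccentricity of any scene point follow from these
#' values. Defaults correspond to a head-mounted stereo display with cameras
#' at x = -0.4 and +0.4 scene units (interpupillary distance 0.8) and a
#' screen-to-viewer distance of 10 scene units.
#'
#' @slot eyeOffset half the interpupillary distance, scene units.
#' @slot fixationDistance distance from the cyclopean point to the fixation
#'   plane (z = 0), scene units.
#' @slot verticalFov,horizontalFov field of view, degrees of visual angle.
#' @slot screenPx screen resolution, integer pair.
#'
#' @export
setClass("ViewerGeometry",
  representation(
    eyeOffset = "numeric",
    fixationDistance = "numeric",
    verticalFov = "numeric",
    horizontalFov = "numeric",
    screenPx = "integer"
  ),
  prototype(
    eyeOffset = 0.4,
    fixationDistance = 10,
    verticalFov = 25,
    horizontalFov = 33,
    screenPx = c(800L, 600L)
  ),
  validity = function(object) {
    msg <- character()
    if (object@eyeOffset <= 0) msg <- c(msg, "eyeOffset must be > 0")
    if (object@fixationDistance <= object@eyeOffset)
      msg <- c(msg, "fixationDistance must exceed eyeOffset")
    if (any(c(object@verticalFov, object@horizontalFov) <= 0) ||
        any(c(object@verticalFov, object@horizontalFov) >= 180))
      msg <- c(msg, "fields of view must lie in (0, 180) degrees")
    if (length(object@screenPx) != 2L || any(object@screenPx <= 0L))
      msg <- c(msg, "screenPx must be two positive integers")
    if (length(msg)) msg else TRUE
  }
)

#' @param eyeOffset,fixationDistance,verticalFov,horizontalFov,screenPx see
#'   slot descriptions.
#' @return a `ViewerGeometry` object.
#' @examples
#' ViewerGeometry()
#' @rdname ViewerGeometry-class
#' @export
ViewerGeometry <- function(eyeOffset = 0.4, fixationDistance = 10,
                           verticalFov = 25, horizontalFov = 33,
                           screenPx = c(800L, 600L)) {
  new("ViewerGeometry",
    eyeOffset = eyeOffset, fixationDistance = fixationDistance,
    verticalFov = verticalFov, horizontalFov = horizontalFov,
    screenPx = as.integer(screenPx))
}

setMethod("show", "ViewerGeometry", function(object) {
  cat("ViewerGeometry\n")
  cat(sprintf("  eye offset        : %.3g scene units (IPD %.3g)\n",
    object@eyeOffset, 2 * object@eyeOffset))
  cat(sprintf("  fixation distance : %.3g scene units\n",
    object@fixationDistance))
  cat(sprintf("  field of view     : %g x %g deg, %d x %d px\n",
    object@horizontalFov, object@verticalFov,
    object@screenPx[1], object@screenPx[2]))
})

#' Staggered triangular grid of stimulus locations
#'
#' Holds the 36 stimulus locations of one run (6 depth rows x 6 columns)
#' together with derived per-location quantities: eccentricity, binocular
#' disparity, and the scene-unit sphere radius that keeps apparent size
#' constant across depth. Mirrored grids (x negated, used on alternate runs)
#' carry `mirrored = TRUE` and keep the column indices of their source
#' columns so that mirrored trials can be re-aligned downstream.
#'
#' @slot locations data.frame with one row per location, columns
#'   `row_index`, `col_index`, `x_scene`, `z_scene`, `ecc_deg`,
#'   `disparity_arcmin`, `sphere_radius_scene`.
#' @slot mirrored logical flag.
#' @slot spacing the spacing configuration used (see [gridSpacing()]).
#' @slot geom the [ViewerGeometry-class] used.
#'
#' @seealso [makeGrid()]
#' @export
setClass("StimulusGrid",
  representation(
    locations = "data.frame",
    mirrored = "logical",
    spacing = "list",
    geom = "ViewerGeometry"
  ),
  validity = function(object) {
    need <- c("row_index", "col_index", "x_scene", "z_scene", "ecc_deg",
      "disparity_arcmin", "sphere_radius_scene")
    miss <- setdiff(need, names(object@locations))
    if (length(miss))
      return(paste("locations is missing columns:", paste(miss, collapse = ", ")))
    if (anyNA(object@locations[need])) return("locations contains NA")
    TRUE
  }
)

setMethod("show", "StimulusGrid", function(object) {
  loc <- object@locations
  cat(sprintf("StimulusGrid: %d locations (%d z rows x %d columns)%s\n",
    nrow(loc), length(unique(loc$z_scene)), length(unique(loc$col_index)),
    if (object@mirrored) ", mirrored" else ""))
  cat(sprintf("  eccentricity %.2f..%.2f deg, disparity %.1f..%.1f arcmin\n",
    min(loc$ecc_deg), max(loc$ecc_deg),
    min(loc$disparity_arcmin), max(loc$disparity_arcmin)))
})

#' Uniform pixel grid over the modeled stimulus axis
#'
#' The discretized 1-D stimulus space on which channel basis functions,
#' stimulus profiles and model-based representations are evaluated.
#'
#' @slot lo,hi domain endpoints, scene units.
#' @slot n number of evenly spaced pixels (>= 2).
#' @slot coords the pixel coordinates, length `n`.
#'
#' @export
setClass("PixelGrid",
  representation(lo = "numeric", hi = "numeric", n = "integer",
    coords = "numeric"),
  validity = function(object) {
    if (object@lo >= object@hi) return("lo must be < hi")
    if (object@n < 2L) return("need at least 2 pixels")
    if (length(object@coords) != object@n) return("coords length != n")
    TRUE
  }
)

#' @param lo,hi domain endpoints in scene units.
#' @param n number of pixels.
#' @return a `PixelGrid`.
#' @details The default (111 pixels over \[-2.75, 2.75\]) gives a pixel
#'   spacing of 0.05 scene units, symmetric about 0, and matches the domain
#'   used for curve fitting.
#' @examples
#' pixelCoords(PixelGrid())[1:5]
#' @rdname PixelGrid-class
#' @export
PixelGrid <- function(lo = -2.75, hi = 2.75, n = 111L) {
  new("PixelGrid", lo = lo, hi = hi, n = as.integer(n),
    coords = seq(lo, hi, length.out = n))
}

setMethod("show", "PixelGrid", function(object) {
  cat(sprintf("PixelGrid: %d pixels over [%g, %g] (spacing %g)\n",
    object@n, object@lo, object@hi, object@coords[2] - object@coords[1]))
})

#' Exponentiated-cosine channel basis
#'
#' A set of spatial channels tiling the stimulus axis. Each channel is a
#' raised cosine taken to a fixed power (default 7), has compact support of
#' half-width `size` scene units, and peaks at its center with value 1. The
#' matrix `F` stores the basis sampled on a [PixelGrid-class] (channels x
#' pixels).
#'
#' @slot centers channel centers, scene units.
#' @slot size half-width of the compact support, scene units.
#' @slot exponent the cosine exponent (fixed at 7 in all defaults).
#' @slot pixels the [PixelGrid-class] the basis is sampled on.
#' @slot F channels x pixels matrix of basis values in \[0, 1\].
#'
#' @seealso [buildBasis()], [basisEval()]
#' @export
setClass("SpatialBasis",
  representation(centers = "numeric", size = "numeric", exponent = "numeric",
    pixels = "PixelGrid", F = "matrix"),
  validity = function(object) {
    if (object@size <= 0) return("size must be > 0")
    if (nrow(object@F) != length(object@centers))
      return("F must have one row per channel center")
    if (ncol(object@F) != object@pixels@n)
      return("F must have one column per pixel")
    if (any(object@F < 0 | object@F > 1)) return("F entries must lie in [0, 1]")
    TRUE
  }
)

setMethod("show", "SpatialBasis", function(object) {
  cat(sprintf(
    "SpatialBasis: %d channels, size %.3g, exponent %g, on %d pixels\n",
    length(object@centers), object@size, object@exponent, object@pixels@n))
  cat("  centers:", paste(format(object@centers), collapse = " "), "\n")
})

#' Trial-by-voxel response container
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding one `response` assay (voxels x trials) plus per-trial metadata in
#' `colData`: `run`, `row_index`, `col_index`, `x`, `z`, `is_null`,
#' `mirrored`. Null trials (no stimulus) carry `is_null = TRUE` and NA
#' position labels; they are excluded from encoding-model and decoding
#' analyses by default.
#'
#' @seealso [TrialExperiment()], [trialResponses()], [trialInfo()]
#' @export
setClass("TrialExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    need <- c("run", "row_index", "col_index", "x", "z", "is_null", "mirrored")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
      return(paste("colData is missing:", paste(miss, collapse = ", ")))
    if (!"response" %in% SummarizedExperiment::assayNames(object))
      return("assay 'response' is required")
    a <- assay(object, "response")
    if (anyNA(a)) return("responses must not contain NA")
    info <- colData(object)
    if (anyNA(info$run)) return("run labels must not contain NA")
    stim <- !info$is_null
    if (any(stim) && anyNA(info$x[stim]))
      return("stimulus trials must have position labels")
    TRUE
  }
)

#' Construct a TrialExperiment
#'
#' @param responses numeric matrix, voxels x trials.
#' @param info data.frame of per-trial metadata with columns `run`,
#'   `row_index`, `col_index`, `x`, `z`, `is_null`, `mirrored`.
#' @return a [TrialExperiment-class].
#' @export
TrialExperiment <- function(responses, info) {
  responses <- as.matrix(responses)
  if (ncol(responses) != nrow(info))
    stop("one metadata row per trial (column of 'responses') is required")
  if (is.null(rownames(responses)))
    rownames(responses) <- paste0("voxel", seq_len(nrow(responses)))
  se <- SummarizedExperiment(
    assays = list(response = responses),
    colData = DataFrame(info))
  new("TrialExperiment", se)
}

setMethod("show", "TrialExperiment", function(object) {
  info <- colData(object)
  cat(sprintf(
    "TrialExperiment: %d voxels x %d trials (%d runs, %d null trials)\n",
    nrow(object), ncol(object), length(unique(info$run)), sum(info$is_null)))
})

#' Ground-truth voxel population for simulation
#'
#' Voxels with known spatial tuning: each voxel mixes a set of generative
#' channels (per axis) with fixed nonnegative weights, so its noiseless
#' response to a stimulus is the weighted sum of channel activations at the
#' stimulus coordinate.
#'
#' @slot weights named list (one element per tuned axis, e.g. `x`, `z`) of
#'   voxels x channels weight matrices.
#' @slot centers named list of generative channel centers per axis.
#' @slot size named numeric vector of generative channel sizes per axis.
#' @slot exponent cosine exponent of the generative channels.
#' @slot seed integer seed the population was drawn with.
#'
#' @seealso [makeVoxels()]
#' @export
setClass("VoxelPopulation",
  representation(weights = "list", centers = "list", size = "numeric",
    exponent = "numeric", seed = "integer"),
  validity = function(object) {
    if (!length(object@weights)) return("at least one tuned axis is required")
    if (!identical(names(object@weights), names(object@centers)))
      return("weights and centers must cover the same axes")
    for (ax in names(object@weights)) {
      W <- object@weights[[ax]]
      if (!is.matrix(W) || anyNA(W) || any(!is.finite(W)))
        return("weight matrices must be finite")
      if (ncol(W) != length(object@centers[[ax]]))
        return("one weight column per generative channel is required")
    }
    TRUE
  }
)

setMethod("show", "VoxelPopulation", function(object) {
  cat(sprintf("VoxelPopulation: %d voxels, axes {%s}, %d channels/axis\n",
    nrow(object@weights[[1]]), paste(names(object@weights), collapse = ", "),
    ncol(object@weights[[1]])))
})

#' A simulated multi-subject experiment
#'
#' Bundles per-subject [TrialExperiment-class] objects with the ground-truth
#' voxel populations and the stimulus grids that generated them. The entire
#' object is a pure function of the simulation configuration and seed.
#'
#' @slot subjects list of `TrialExperiment`, one per subject.
#' @slot voxels list of [VoxelPopulation-class], one per subject.
#' @slot gridBase,gridMirror the unmirrored and mirrored [StimulusGrid-class].
#' @slot noiseSd numeric vector of the absolute trial noise SD used per subject.
#' @slot seed integer master seed.
#' @slot config the simulation settings used.
#'
#' @seealso [simulateExperiment()]
#' @export
setClass("SimulatedExperiment",
  representation(subjects = "list", voxels = "list",
    gridBase = "StimulusGrid", gridMirror = "StimulusGrid",
    noiseSd = "numeric", seed = "integer", config = "list"),
  validity = function(object) {
    if (length(object@subjects) != length(object@voxels))
      return("one voxel population per subject is required")
    if (!all(vapply(object@subjects, is, TRUE, "TrialExperiment")))
      return("subjects must be TrialExperiment objects")
    TRUE
  }
)

setMethod("show", "SimulatedExperiment", function(object) {
  te <- object@subjects[[1]]
  cat(sprintf(
    "SimulatedExperiment: %d subjects, %d runs x %d trials, %d voxels\n",
    length(object@subjects), length(unique(colData(te)$run)),
    sum(colData(te)$run == colData(te)$run[1]), nrow(te)))
  cat(sprintf("  seed %d, noise sd %s\n", object@seed,
    paste(format(unique(round(object@noiseSd, 4))), collapse = "/")))
})

#' Model-based stimulus representations
#'
#' Pixel-space curves obtained by projecting estimated channel responses
#' back through the basis: one row per trial (or per averaged position).
#'
#' @slot curves rows x pixels matrix of representation values.
#' @slot pixels the [PixelGrid-class] of the columns.
#' @slot info data.frame with one row of labels per curve.
#'
#' @seealso [reconstruct()], [crossvalReconstruct()], [averageByPosition()]
#' @export
setClass("Reconstruction",
  representation(curves = "matrix", pixels = "PixelGrid", info = "data.frame"),
  validity = function(object) {
    if (ncol(object@curves) != object@pixels@n)
      return("curves must have one column per pixel")
    if (nrow(object@info) && nrow(object@info) != nrow(object@curves))
      return("info must have one row per curve")
    TRUE
  }
)

setMethod("show", "Reconstruction", function(object) {
  cat(sprintf("Reconstruction: %d curve(s) on %d pixels over [%g, %g]\n",
    nrow(object@curves), object@pixels@n, object@pixels@lo, object@pixels@hi))
})

#' Fitted exponentiated-cosine curve
#'
#' Parameters of the best fit `b + a * (0.5 cos(|x - c| pi / s) + 0.5)^7`
#' (zero-centered term outside `|x - c| < s`) to one model-based
#' representation, with the achieved root-mean-squared error and the stage
#' that produced it (`"grid"` exhaustive search or `"refined"` bounded local
#' optimization).
#'
#' @slot center,size,amplitude,baseline fitted parameters (scene/response units).
#' @slot rmse root-mean-squared error of the returned fit.
#' @slot gridRmse RMSE of the grid stage (never below `rmse`).
#' @slot stage `"grid"` or `"refined"`.
#'
#' @seealso [fitRepresentation()], [gridFit()]
#' @export
setClass("CurveFit",
  representation(center = "numeric", size = "numeric", amplitude = "numeric",
    baseline = "numeric", rmse = "numeric", gridRmse = "numeric",
    stage = "character"),
  validity = function(object) {
    if (object@size <= 0) return("size must be > 0")
    if (object@amplitude < 0) return("amplitude must be >= 0")
    if (object@rmse < 0) return("rmse must be >= 0")
    TRUE
  }
)

setMethod("show", "CurveFit", function(object) {
  cat(sprintf(
    "CurveFit (%s): c = %.4g, s = %.4g, a = %.4g, b = %.4g, rmse = %.4g\n",
    object@stage, object@center, object@size, object@amplitude,
    object@baseline, object@rmse))
})

#' Bootstrap distribution of a group statistic
#'
#' Values of a statistic across bootstrap resamples of subjects, with the
#' point estimate on the original sample and percentile confidence bounds.
#'
#' @slot values iterations x statistics matrix of resampled values.
#' @slot point named numeric point estimate(s) on the original sample.
#' @slot ciLower,ciUpper percentile CI bounds.
#' @slot level confidence level (default 0.95).
#' @slot nIter number of resampling iterations.
#' @slot seed integer seed.
#'
#' @seealso [bootstrapSubjects()]
#' @export
setClass("BootstrapDistribution",
  representation(values = "matrix", point = "numeric", ciLower = "numeric",
    ciUpper = "numeric", level = "numeric", nIter = "integer",
    seed = "integer"),
  validity = function(object) {
    if (nrow(object@values) != object@nIter)
      return("values must have nIter rows")
    if (length(object@point) != ncol(object@values))
      return("one point estimate per statistic is required")
    TRUE
  }
)

setMethod("show", "BootstrapDistribution", function(object) {
  cat(sprintf("BootstrapDistribution: %d iterations, %d statistic(s)\n",
    object@nIter, ncol(object@values)))
  for (j in seq_along(object@point)) {
    nm <- names(object@point)[j] %||% paste0("stat", j)
    cat(sprintf("  %s = %.4g [%.4g, %.4g]\n", nm, object@point[j],
      object@ciLower[j], object@ciUpper[j]))
  }
})
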