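#' Fitting grid specification
#'
#' Search ranges for the two-stage curve fit: an exhaustive grid over
#' candidate centers and sizes (with the amplitude and baseline solved by
#' linear regression at each grid point), followed by a bounded local
#' refinement. Defaults: centers -2.75 to 2.75 scene units in steps of 0.1
#' (the region of visual stimulation), sizes 1.5 to 15 in steps of 0.1,
#' baseline bounded in \[-5, 5\], amplitude bounded in \[0, max - min\] of
#' the curve, and a refinement box of one grid step (0.1) around the grid
#' optimum.
#'
#' @param centerRange,centerStep,sizeRange,sizeStep grid geometry.
#' @param baselineBounds allowed baseline interval.
#' @param refineBox half-width of the refinement box for center and size.
#' @return a list of class `fitGridSpec`.
#' @export
fitGridSpec <- function(centerRange = c(-2.75, 2.75), centerStep = 0.1,
                        sizeRange = c(1.5, 15), sizeStep = 0.1,
                        baselineBounds = c(-5, 5), refineBox = 0.1) {
  if (centerStep <= 0 || sizeStep <= 0) stop("grid steps must be > 0")
  if (diff(centerRange) < 0 || diff(sizeRange) < 0)
    stop("grid ranges must be nonempty")
  structure(list(centerRange = centerRange, centerStep = centerStep,
    sizeRange = sizeRange, sizeStep = sizeStep,
    baselineBounds = baselineBounds, refineBox = refineBox),
    class = "fitGridSpec")
}

#' Evaluate the representation-fitting curve
#'
#' `f(x) = b + a (0.5 cos(|x - c| pi / s) + 0.5)^7`, equal to `b` wherever
#' `|x - c| >= s`: the channel profile of [basisEval()] with added
#' amplitude and baseline.
#'
#' @param x pixel coordinate(s).
#' @param center,size,amplitude,baseline curve parameters.
#' @param exponent cosine exponent.
#' @return curve values at `x`.
#' @export
curveEval <- function(x, center, size, amplitude, baseline, exponent = 7) {
  baseline + amplitude * basisEval(abs(x - center), size, exponent)
}

#' Precompute the exhaustive fitting grid
#'
#' Evaluates the unit-amplitude curve for every (center, size) combination
#' on the pixel grid once, so that many curves can be fitted against the
#' same grid cheaply. Combinations are ordered by center, then size; ties
#' in RMSE are broken in that order.
#'
#' @param pixels a [PixelGrid-class].
#' @param spec a [fitGridSpec()].
#' @return an opaque list consumed by [gridFit()] and [fitRepresentation()].
#' @export
precomputeFitGrid <- function(pixels = PixelGrid(), spec = fitGridSpec()) {
  centers <- seq(spec$centerRange[1], spec$centerRange[2], by = spec$centerStep)
  sizes <- seq(spec$sizeRange[1], spec$sizeRange[2], by = spec$sizeStep)
  combos <- expand.grid(size = sizes, center = centers)  # center varies slowest
  px <- pixelCoords(pixels)
  G <- basisEval(abs(outer(combos$center, px, "-")), combos$size)
  list(combos = combos, G = G, Sg = rowSums(G), Sgg = rowSums(G * G),
    n = length(px), pixels = pixels, spec = spec)
}

# bounded (a, b) regression of y on a unit curve g, given its sufficient
# statistics; exact for this box-constrained 2-parameter problem: solve
# unconstrained, clamp a, re-solve b, clamp b.
solveAmpBase <- function(Sg, Sgg, Sgy, Sy, n, aMax, bBounds) {
  den <- n * Sgg - Sg^2
  a <- ifelse(den > 1e-12, (n * Sgy - Sg * Sy) / den, 0)
  a <- clamp(a, 0, aMax)
  b <- clamp((Sy - a * Sg) / n, bBounds[1], bBounds[2])
  list(a = a, b = b)
}

#' Exhaustive grid-search curve fit
#'
#' Stage one of the two-stage fit: for every (center, size) grid point the
#' amplitude and baseline are solved by linear regression with the
#' amplitude restricted to \[0, max(curve) - min(curve)\], and the
#' combination with the lowest root-mean-squared error is returned
#' (deterministic tie-break: smallest center, then smallest size). A
#' constant curve yields an amplitude-0 fit at its value.
#'
#' @param curve numeric vector of representation values, one per pixel.
#' @param pixels a [PixelGrid-class] matching `curve`.
#' @param spec a [fitGridSpec()].
#' @param pre optional precomputed grid from [precomputeFitGrid()].
#' @return a [CurveFit-class] with `stage = "grid"`.
#' @export
gridFit <- function(curve, pixels = PixelGrid(), spec = fitGridSpec(),
                    pre = NULL) {
  if (anyNA(curve) || any(!is.finite(curve)))
    stop("curve must be finite")
  pre <- pre %||% precomputeFitGrid(pixels, spec)
  if (length(curve) != pre$n)
    stop("curve length does not match the pixel grid")
  n <- pre$n
  Sy <- sum(curve); Syy <- sum(curve^2)
  Sgy <- as.vector(pre$G %*% curve)
  aMax <- max(curve) - min(curve)
  ab <- solveAmpBase(pre$Sg, pre$Sgg, Sgy, Sy, n, aMax, pre$spec$baselineBounds)
  rss <- Syy + ab$a^2 * pre$Sgg + n * ab$b^2 -
    2 * ab$a * Sgy - 2 * ab$b * Sy + 2 * ab$a * ab$b * pre$Sg
  rmse <- sqrt(pmax(rss, 0) / n)
  i <- which.min(rmse)   # first minimum = smallest center, then size
  new("CurveFit", center = pre$combos$center[i], size = pre$combos$size[i],
    amplitude = ab$a[i], baseline = ab$b[i], rmse = rmse[i],
    gridRmse = rmse[i], stage = "grid")
}

#' Two-stage constrained curve fit
#'
#' Runs [gridFit()] and then refines all four parameters with a bounded
#' local optimizer (`L-BFGS-B`), constraining center and size to within one
#' grid step of the grid optimum, the baseline to its bounds, and the
#' amplitude to \[0, max - min\]. If refinement fails or increases the
#' RMSE, the grid fit is returned unchanged.
#'
#' @inheritParams gridFit
#' @return a [CurveFit-class]; `stage` records whether refinement won.
#' @examples
#' px <- PixelGrid()
#' y <- curveEval(pixelCoords(px), 0.55, 3, 1, 0)
#' fitParams(fitRepresentation(y))[["center"]]   # ~0.55
#' @export
fitRepresentation <- function(curve, pixels = PixelGrid(),
                              spec = fitGridSpec(), pre = NULL) {
  pre <- pre %||% precomputeFitGrid(pixels, spec)
  g <- gridFit(curve, pixels, spec, pre)
  px <- pixelCoords(pre$pixels)
  aMax <- max(curve) - min(curve)
  obj <- function(p) {
    sqrt(mean((curve - curveEval(px, p[1], p[2], p[3], p[4]))^2))
  }
  start <- c(g@center, g@size, g@amplitude, g@baseline)
  lower <- c(g@center - spec$refineBox, max(g@size - spec$refineBox, 1e-6),
    0, spec$baselineBounds[1])
  upper <- c(g@center + spec$refineBox, g@size + spec$refineBox,
    aMax, spec$baselineBounds[2])
  ref <- tryCatch(
    optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(factr = 1e4)),
    error = function(e) NULL)
  if (is.null(ref)) {
    warning("refinement optimizer failed; keeping the grid fit")
    return(g)
  }
  if (ref$value < g@rmse) {
    new("CurveFit", center = ref$par[1], size = ref$par[2],
      amplitude = ref$par[3], baseline = ref$par[4], rmse = ref$value,
      gridRmse = g@rmse, stage = "refined")
  } else {
    g
  }
}

#' Fit every curve of a reconstruction
#'
#' Applies [fitRepresentation()] to each row of a (typically
#' position-averaged) [Reconstruction-class] and tabulates the results.
#'
#' @param recon a [Reconstruction-class].
#' @param spec a [fitGridSpec()].
#' @param pre optional precomputed grid (shared across calls).
#' @return data.frame: the reconstruction's `info` columns plus `center`,
#'   `size`, `amplitude`, `baseline`, `rmse`, `stage`, and `center_error`
#'   when a `true_coord` column is present.
#' @export
fitReconstruction <- function(recon, spec = fitGridSpec(), pre = NULL) {
  pre <- pre %||% precomputeFitGrid(recon@pixels, spec)
  curves <- reconCurves(recon)
  fits <- lapply(seq_len(nrow(curves)), function(i)
    fitRepresentation(curves[i, ], recon@pixels, spec, pre))
  out <- data.frame(
    center = vapply(fits, slot, 0, "center"),
    size = vapply(fits, slot, 0, "size"),
    amplitude = vapply(fits, slot, 0, "amplitude"),
    baseline = vapply(fits, slot, 0, "baseline"),
    rmse = vapply(fits, slot, 0, "rmse"),
    stage = vapply(fits, slot, "", "stage"))
  info <- reconInfo(recon)
  if (nrow(info)) {
    out <- cbind(info, out)
    if ("true_coord" %in% names(info))
      out$center_error <- centerError(out$center, out$true_coord)
  }
  out
}

#' Absolute center error of a fit
#'
#' `|c - true|`: the absolute difference between a fitted representation
#' center and the displayed stimulus coordinate, in scene units.
#'
#' @param fit a [CurveFit-class] or numeric fitted center(s).
#' @param truePosition the displayed coordinate(s).
#' @return nonnegative error(s) in scene units.
#' @export
centerError <- function(fit, truePosition) {
  center <- if (is(fit, "CurveFit")) fit@center else fit
  abs(center - truePosition)
}
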