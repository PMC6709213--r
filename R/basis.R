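#' Exponentiated-cosine channel profile
#'
#' The canonical channel shape: `(0.5 cos(r pi / s) + 0.5)^exponent` for
#' `r < s` and 0 elsewhere, where `r >= 0` is the distance from the channel
#' center and `s > 0` its size (half-width of the compact support). With the
#' default exponent 7 this gives a Gaussian-like bump that reaches exactly 1
#' at `r = 0` and falls to `0.5^7 = 0.0078125` at `r = s/2`.
#'
#' @param r distance(s) from the channel center; may be a vector or matrix.
#' @param s channel size; scalar, or a vector recycled along the rows of a
#'   matrix `r`.
#' @param exponent the cosine exponent.
#' @return basis values in \[0, 1\], same shape as `r`.
#' @examples
#' basisEval(0, 1.8)          # 1
#' basisEval(0.9, 1.8)        # 0.5^7
#' basisEval(2.5, 1.8)        # 0 (outside the support)
#' @export
basisEval <- function(r, s, exponent = 7) {
  if (any(s <= 0)) stop("channel size 's' must be > 0")
  if (any(r < 0)) stop("'r' is a distance and must be >= 0")
  out <- (0.5 * cos(pi * r / s) + 0.5)^exponent
  out[r >= s] <- 0
  out
}

#' Build a channel basis on a pixel grid
#'
#' Evaluates `n` exponentiated-cosine channels at every pixel, yielding the
#' channels x pixels matrix `F` used both to build design matrices (via the
#' stimulus profile) and to project estimated channel responses back into
#' pixel space. The default 6 channels sit at the six stimulus row
#' coordinates (-1.5 to 1.5, spacing 0.6 scene units) with size 1.8, evenly
#' tiling the modeled axis.
#'
#' @param nChannels number of channels; must equal `length(centers)`.
#' @param pixels a [PixelGrid-class].
#' @param centers channel centers (scene units), strictly increasing and
#'   inside the pixel domain.
#' @param size channel size (scene units).
#' @param exponent cosine exponent.
#' @return a [SpatialBasis-class].
#' @examples
#' b <- buildBasis()
#' dim(basisMatrix(b))   # 6 x 111
#' @export
buildBasis <- function(nChannels = 6L, pixels = PixelGrid(),
                       centers = seq(-1.5, 1.5, length.out = 6),
                       size = 1.8, exponent = 7) {
  if (length(centers) != nChannels)
    stop("nChannels (", nChannels, ") must match length(centers) (",
      length(centers), ")")
  if (is.unsorted(centers, strictly = TRUE))
    stop("centers must be strictly increasing")
  if (min(centers) < pixels@lo || max(centers) > pixels@hi)
    stop("centers must lie within the pixel domain")
  R <- abs(outer(centers, pixelCoords(pixels), "-"))
  F <- basisEval(R, size, exponent)
  new("SpatialBasis", centers = centers, size = size, exponent = exponent,
    pixels = pixels, F = F)
}

#' Pixel representation of a stimulus
#'
#' Encodes one stimulus coordinate as a nonnegative column over the pixel
#' grid with unit total mass. `"delta"` mode puts all mass on the nearest
#' pixel; `"boxcar"` spreads it uniformly over pixels within `extent` scene
#' units of the coordinate (e.g. the sphere radius).
#'
#' @param coord stimulus coordinate on the modeled axis, scene units.
#' @param pixels a [PixelGrid-class].
#' @param mode `"delta"` or `"boxcar"`.
#' @param extent boxcar half-width in scene units (required for boxcar).
#' @return numeric vector of length `pixels@n`, summing to 1.
#' @export
stimulusProfile <- function(coord, pixels = PixelGrid(),
                            mode = c("delta", "boxcar"), extent = NULL) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(coord, "coord")
  px <- pixelCoords(pixels)
  if (coord < pixels@lo || coord > pixels@hi)
    stop(sprintf("stimulus coordinate %.3g outside the pixel domain [%g, %g]",
      coord, pixels@lo, pixels@hi))
  out <- numeric(pixels@n)
  if (mode == "delta") {
    out[which.min(abs(px - coord))] <- 1
  } else {
    if (is.null(extent) || extent <= 0)
      stop("boxcar mode requires a positive 'extent'")
    spacing <- px[2] - px[1]
    hit <- abs(px - coord) <= extent + spacing * 1e-6
    out[hit] <- 1 / sum(hit)
  }
  out
}

#' @param coords vector of stimulus coordinates (one trial each).
#' @return `stimulusProfileMatrix` returns the pixels x trials matrix `S`.
#' @rdname stimulusProfile
#' @export
stimulusProfileMatrix <- function(coords, pixels = PixelGrid(),
                                  mode = c("delta", "boxcar"), extent = NULL) {
  mode <- match.arg(mode)
  vapply(coords, stimulusProfile, numeric(pixels@n),
    pixels = pixels, mode = mode, extent = extent)
}
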