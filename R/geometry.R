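#' Binocular disparity of a scene point
#'
#' Relative disparity of the point `(x, z)` with respect to the fixation
#' point, under the vergence model: with the two eyes at `+-e` on the x-axis
#' and fixation straight ahead at distance `D`, the disparity of a point at
#' horizontal offset `x` and depth `z` (positive z = nearer to the viewer,
#' the point sits at viewing distance `D - z`) is
#' \deqn{2\,\mathrm{atan}(e/D) - \left[\mathrm{atan}\!\frac{x+e}{D-z} -
#'   \mathrm{atan}\!\frac{x-e}{D-z}\right]}
#' converted to arcminutes. Negative values are crossed (near) disparities,
#' positive values uncrossed (far), and a point on the fixation plane has
#' disparity exactly 0.
#'
#' @param x,z scene-unit coordinates of the point(s); vectorized.
#' @param geom a [ViewerGeometry-class].
#' @return disparity in arcminutes (numeric, same length as `x`/`z`).
#' @examples
#' disparityOfPoint(0, 1.5)   # nearest depth row, on axis: about -48.4
#' disparityOfPoint(0, 0)     # fixation plane: exactly 0
#' @export
disparityOfPoint <- function(x, z, geom = ViewerGeometry()) {
  e <- geom@eyeOffset
  D <- geom@fixationDistance
  d <- D - z
  if (any(d <= 0))
    stop("invalid geometry: point at or behind the eyes (fixationDistance - z <= 0)")
  rad <- 2 * atan2(e, D) - (atan2(x + e, d) - atan2(x - e, d))
  rad * (180 / pi) * 60
}

#' Eccentricity of a scene point
#'
#' Visual angle between the fixation direction and the point, measured from
#' the cyclopean point: `atan(|x| / (D - z))` in degrees. Symmetric in the
#' sign of `x`.
#'
#' @inheritParams disparityOfPoint
#' @return eccentricity in degrees of visual angle.
#' @export
sceneToEcc <- function(x, z, geom = ViewerGeometry()) {
  d <- geom@fixationDistance - z
  if (any(d <= 0))
    stop("invalid geometry: point at or behind the eyes (fixationDistance - z <= 0)")
  atan2(abs(x), d) * 180 / pi
}

#' Scene-unit sphere radius at a given depth
#'
#' Radius that keeps the apparent (angular) size of the sphere stimulus
#' constant across depth: linear interpolation in viewing distance
#' `d = D - z`, anchored at the rendered extremes (d = 11.5 -> 0.73 scene
#' units at the farthest row, d = 8.5 -> 0.55 at the nearest row).
#' Extrapolation outside the anchored range is permitted with a warning.
#'
#' @inheritParams disparityOfPoint
#' @param anchorsD viewing distances of the two anchors.
#' @param anchorsR scene-unit radii at the anchors.
#' @return sphere radius in scene units.
#' @examples
#' sphereRadiusAt(c(-1.5, 0, 1.5))  # 0.73, 0.64, 0.55
#' @export
sphereRadiusAt <- function(z, geom = ViewerGeometry(),
                           anchorsD = c(8.5, 11.5),
                           anchorsR = c(0.55, 0.73)) {
  d <- geom@fixationDistance - z
  if (any(d < min(anchorsD) | d > max(anchorsD)))
    warning("extrapolating sphere radius outside the anchored depth range")
  slope <- diff(anchorsR) / diff(anchorsD)
  anchorsR[1] + (d - anchorsD[1]) * slope
}

#' Printed per-row average disparities of the stimulus grid
#'
#' The six unique depth rows of the stimulus grid with their published
#' row-average binocular disparities (arcminutes, negative = crossed/near).
#' These averages are the reference depth separations used by the pairwise
#' decoding scheme; [makeGrid()] reproduces them to within ~0.2 arcmin from
#' the geometry alone.
#'
#' @return data.frame with columns `z_scene` and `disparity_arcmin`.
#' @examples
#' depthRowDisparities()
#' @export
depthRowDisparities <- function() {
  data.frame(
    z_scene = c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5),
    disparity_arcmin = c(38.6, 25.6, 11.1, -5.2, -23.6, -44.6))
}
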