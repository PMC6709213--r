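#' Spacing configuration for the stimulus grid
#'
#' The default grid places 6 columns (3 left, 3 right of fixation) in each
#' of the 6 depth rows. Column positions are defined in eccentricity
#' (degrees) and converted to scene units per row with `x = (D - z) tan(theta)`,
#' so every row spans the same eccentricity range. Within a row the unsigned
#' eccentricities are evenly spaced over `eccRange`; alternate rows are
#' staggered by +- a quarter of the column spacing (half a spacing between
#' adjacent rows), which makes the grid triangular and guarantees that a
#' grid and its horizontal mirror sample 12 distinct columns per row.
#'
#' @param geom a [ViewerGeometry-class].
#' @param zRows scene-unit z of the six depth rows (positive = nearer).
#' @param eccRange eccentricity range (degrees) spanned by the grid.
#' @param nCols number of columns per row (even; half on each side).
#' @return a list with the resolved spacing parameters, consumed by
#'   [makeGrid()].
#' @export
gridSpacing <- function(geom = ViewerGeometry(),
                        zRows = c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5),
                        eccRange = c(0.9, 9.8), nCols = 6L) {
  nCols <- as.integer(nCols)
  if (nCols < 2L || nCols %% 2L != 0L)
    stop("nCols must be an even number of columns")
  if (eccRange[1] <= 0 || eccRange[2] <= eccRange[1])
    stop("eccRange must be increasing and positive")
  nSide <- nCols %/% 2L
  # |theta| grid: nSide values per side with quarter-step stagger; across
  # both stagger phases the unsigned eccentricities evenly fill eccRange.
  thetaStep <- diff(eccRange) / (nSide - 0.5)
  thetaInner <- eccRange[1] + thetaStep / 4
  list(zRows = zRows, eccRange = eccRange, nCols = nCols,
    thetaInner = thetaInner, thetaStep = thetaStep)
}

#' Construct the staggered triangular stimulus grid
#'
#' Builds the 36-location grid (6 depth rows x 6 columns) of one run.
#' Mirrored grids negate every `x_scene` (used on alternate runs so that a
#' run pair samples 72 distinct locations) while keeping each location's
#' `col_index` from the base layout, so mirrored trials can later be folded
#' back onto the base columns.
#'
#' @param geom a [ViewerGeometry-class].
#' @param spacing spacing configuration from [gridSpacing()].
#' @param mirrored logical; negate all x coordinates.
#' @return a [StimulusGrid-class].
#' @examples
#' g <- makeGrid()
#' nrow(gridLocations(g))            # 36
#' range(gridLocations(g)$ecc_deg)   # 0.9 .. 9.8
#' @export
makeGrid <- function(geom = ViewerGeometry(), spacing = gridSpacing(geom),
                     mirrored = FALSE) {
  zRows <- spacing$zRows
  nSide <- spacing$nCols %/% 2L
  D <- geom@fixationDistance
  rows <- lapply(seq_along(zRows), function(r) {
    z <- zRows[r]
    phase <- if (r %% 2L == 1L) 1 else -1
    # signed column eccentricities, ordered left to right
    thetaBase <- c(-rev(spacing$thetaInner + (seq_len(nSide) - 1) * spacing$thetaStep),
      spacing$thetaInner + (seq_len(nSide) - 1) * spacing$thetaStep)
    theta <- thetaBase + phase * spacing$thetaStep / 4
    x <- (D - z) * tan(theta * pi / 180)
    data.frame(row_index = r, col_index = seq_len(spacing$nCols),
      x_scene = x, z_scene = z)
  })
  loc <- do.call(rbind, rows)
  if (mirrored) loc$x_scene <- -loc$x_scene
  loc$ecc_deg <- sceneToEcc(loc$x_scene, loc$z_scene, geom)
  loc$disparity_arcmin <- disparityOfPoint(loc$x_scene, loc$z_scene, geom)
  loc$sphere_radius_scene <- sphereRadiusAt(loc$z_scene, geom)
  if (max(loc$ecc_deg) > geom@horizontalFov / 2)
    stop(sprintf(
      "spacing places stimuli at %.1f deg, outside the displayable half-field (%.1f deg)",
      max(loc$ecc_deg), geom@horizontalFov / 2))
  new("StimulusGrid", locations = loc, mirrored = mirrored,
    spacing = spacing, geom = geom)
}

#' Export / import a stimulus grid as CSV
#'
#' Writes (or reads back) the per-location table with columns `row_index`,
#' `col_index`, `x_scene`, `z_scene`, `ecc_deg`, `disparity_arcmin`,
#' `sphere_radius_scene`. Import recomputes nothing: the file is taken as
#' the authoritative location list.
#'
#' @param grid a [StimulusGrid-class].
#' @param path file path.
#' @return `exportGrid` returns `path` invisibly; `importGrid` returns a
#'   `StimulusGrid`.
#' @export
exportGrid <- function(grid, path) {
  write.csv(gridLocations(grid), path, row.names = FALSE)
  invisible(path)
}

#' @param geom geometry to attach to the imported grid.
#' @param mirrored mirrored flag to attach to the imported grid.
#' @rdname exportGrid
#' @export
importGrid <- function(path, geom = ViewerGeometry(), mirrored = FALSE) {
  loc <- read.csv(path)
  new("StimulusGrid", locations = loc, mirrored = mirrored,
    spacing = list(), geom = geom)
}
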