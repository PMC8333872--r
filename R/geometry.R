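#' Screen and viewing geometry
#'
#' Describes the physical display, its pixel raster and the viewing distance.
#' This object is the single authority for all pixel/millimetre/degree
#' conversions in the package. Defaults describe a 27-inch 1440p display
#' (595 x 335 mm, 2560 x 1440 px) viewed from 500 mm.
#'
#' @param width_mm,height_mm Physical screen size in millimetres.
#' @param width_px,height_px Screen resolution in pixels.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_error_to_dva(100, geom)
#' @export
screen_geometry <- function(width_mm = 595, height_mm = 335,
                            width_px = 2560, height_px = 1440,
                            viewing_distance_mm = 500) {
  vals <- c(width_mm, height_mm, width_px, height_px, viewing_distance_mm)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be finite and strictly positive")
  }
  structure(
    list(width_mm = width_mm, height_mm = height_mm,
         width_px = width_px, height_px = height_px,
         viewing_distance_mm = viewing_distance_mm),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g px (%g x %g mm) viewed at %g mm\n",
              x$width_px, x$height_px, x$width_mm, x$height_mm,
              x$viewing_distance_mm))
  invisible(x)
}

assert_geometry <- function(geom) {
  if (!inherits(geom, "screen_geometry")) {
    stop("`geom` must be a screen_geometry object")
  }
  geom
}

#' Convert a pixel error magnitude to degrees of visual angle
#'
#' Uses the width-based small-target conversion
#' \deqn{E_{dva} = \arctan\left(\frac{E_{px}}{d_{mm}} \cdot
#'   \frac{sw_{mm}}{sw_{px}}\right) \cdot \frac{180}{\pi}}
#' where `d_mm` is the viewing distance and `sw_mm`/`sw_px` the screen width
#' in millimetres and pixels. The conversion deliberately uses the screen
#' width only, also for two-dimensional error magnitudes; no anisotropic or
#' eccentricity-dependent correction is applied.
#'
#' @param error_px Non-negative error magnitude(s) in screen pixels.
#' @param geom A [screen_geometry()].
#' @return Error magnitude(s) in degrees of visual angle (dva).
#' @seealso [dva_to_px_error()] for the inverse.
#' @export
px_error_to_dva <- function(error_px, geom = screen_geometry()) {
  assert_geometry(geom)
  if (length(error_px) == 0 || !all(is.finite(error_px))) {
    stop("`error_px` must be finite")
  }
  if (any(error_px < 0)) {
    stop("`error_px` must be non-negative (it is an error magnitude)")
  }
  atan(error_px * geom$width_mm / (geom$viewing_distance_mm * geom$width_px)) *
    180 / pi
}

#' Convert degrees of visual angle to a pixel error magnitude
#'
#' Exact inverse of [px_error_to_dva()]: `tan(dva) * d_mm * sw_px / sw_mm`.
#'
#' @param dva Angle(s) in degrees, in `[0, 90)`.
#' @param geom A [screen_geometry()].
#' @return Error magnitude(s) in screen pixels.
#' @export
dva_to_px_error <- function(dva, geom = screen_geometry()) {
  assert_geometry(geom)
  if (length(dva) == 0 || !all(is.finite(dva))) stop("`dva` must be finite")
  if (any(dva < 0) || any(dva >= 90)) {
    stop("`dva` must lie in [0, 90): the tangent is undefined at 90 degrees")
  }
  tan(dva * pi / 180) * geom$viewing_distance_mm * geom$width_px / geom$width_mm
}

#' Tile the screen into square regions
#'
#' Divides the screen into an `n_cols` x `n_rows` grid of square tiles of side
#' `edge_px`. Partial tiles at the right and bottom edges count as regions
#' (ceiling rule), so a 2560 x 1440 screen gives 15 tiles at edge 530 and 144
#' tiles at edge 160.
#'
#' @param geom A [screen_geometry()].
#' @param edge_px Tile side length in pixels; must be positive and no larger
#'   than the larger screen dimension.
#' @return An object of class `tile_grid` with fields `edge_px`, `n_cols`,
#'   `n_rows` and the generating `geom`.
#' @export
tile_screen <- function(geom = screen_geometry(), edge_px) {
  assert_geometry(geom)
  if (length(edge_px) != 1 || !is.finite(edge_px) || edge_px <= 0) {
    stop("`edge_px` must be a single positive number")
  }
  if (edge_px > max(geom$width_px, geom$height_px)) {
    stop("`edge_px` exceeds both screen dimensions")
  }
  structure(
    list(edge_px = edge_px,
         n_cols = as.integer(ceiling(geom$width_px / edge_px)),
         n_rows = as.integer(ceiling(geom$height_px / edge_px)),
         geom = geom),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %g px (%d total)\n",
              x$n_cols, x$n_rows, x$edge_px, n_tiles(x)))
  invisible(x)
}

#' Number of tiles in a grid
#' @param grid A [tile_screen()] grid.
#' @return Integer tile count `n_cols * n_rows`.
#' @export
n_tiles <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  grid$n_cols * grid$n_rows
}

#' Map screen points to tiles
#'
#' Screen coordinates are 0-based and continuous, origin at the top-left
#' corner, x rightward and y downward. Points exactly on the right/bottom
#' screen edge belong to the last tile, so every on-screen point maps to
#' exactly one tile.
#'
#' @param grid A [tile_screen()] grid.
#' @param x,y Screen coordinates in pixels.
#' @return A data frame with 1-based `col`, `row` and a linear `tile` id
#'   (`(row - 1) * n_cols + col`).
#' @export
tile_index <- function(grid, x, y) {
  stopifnot(inherits(grid, "tile_grid"))
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("points must be finite")
  g <- grid$geom
  if (any(x < 0 | x > g$width_px | y < 0 | y > g$height_px)) {
    stop("points must lie on the screen")
  }
  col <- pmin(floor(x / grid$edge_px) + 1L, grid$n_cols)
  row <- pmin(floor(y / grid$edge_px) + 1L, grid$n_rows)
  data.frame(col = as.integer(col), row = as.integer(row),
             tile = as.integer((row - 1L) * grid$n_cols + col))
}

#' Eccentricity of screen points
#'
#' Euclidean distance, in pixels, from the screen centre
#' `(width_px / 2, height_px / 2)`.
#'
#' @param x,y Screen coordinates in pixels.
#' @param geom A [screen_geometry()].
#' @return Distance(s) from the screen centre in pixels.
#' @export
eccentricity <- function(x, y, geom = screen_geometry()) {
  assert_geometry(geom)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("points must be finite")
  sqrt((x - geom$width_px / 2)^2 + (y - geom$height_px / 2)^2)
}
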