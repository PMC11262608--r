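#' Screen geometry of the stimulus display
#'
#' Describes the physical display used for the saccade task.  The default
#' instance is the study display: a 23-inch 16:9 monitor at 1920x1080 and
#' 60 Hz, viewed from 65 cm.  All pixel/degree conversions in the package
#' derive from this object under a flat-screen approximation: eccentricity
#' is `atan(planar offset / viewing distance)` measured from the gaze ray
#' through the screen centre.  Pixels are assumed square; the centimetre
#' size of a pixel is computed from the diagonal, aspect ratio and
#' horizontal resolution.
#'
#' @param diagonal_inches Display diagonal in inches.
#' @param aspect_w,aspect_h Aspect ratio (width : height terms).
#' @param res_x,res_y Resolution in pixels.
#' @param refresh_hz Refresh rate in Hz (metadata only).
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' pixels_to_degrees(100, geom)  # ~2.34 degrees
#' @export
screen_geometry <- function(diagonal_inches = 23, aspect_w = 16, aspect_h = 9,
                            res_x = 1920, res_y = 1080, refresh_hz = 60,
                            viewing_distance_cm = 65) {
  fields <- c(diagonal_inches = diagonal_inches, aspect_w = aspect_w,
              aspect_h = aspect_h, res_x = res_x, res_y = res_y,
              refresh_hz = refresh_hz,
              viewing_distance_cm = viewing_distance_cm)
  if (!all(is.finite(fields)) || any(fields <= 0)) {
    stop("all screen_geometry fields must be strictly positive and finite")
  }
  if (abs(res_x / res_y - aspect_w / aspect_h) / (aspect_w / aspect_h) > 0.01) {
    stop("resolution ", res_x, "x", res_y,
         " is inconsistent with aspect ratio ", aspect_w, ":", aspect_h)
  }
  structure(as.list(fields), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %g\" %g:%g, %gx%g px @ %g Hz, viewed from %g cm\n",
    x$diagonal_inches, x$aspect_w, x$aspect_h, x$res_x, x$res_y,
    x$refresh_hz, x$viewing_distance_cm))
  cat(sprintf("  cm/px = %.6f, px/deg at centre = %.2f\n",
              cm_per_pixel(x), degrees_to_pixels(1, x)))
  invisible(x)
}

#' Physical pixel pitch of a display
#'
#' Centimetres per pixel, derived from the diagonal, the aspect ratio and
#' the horizontal resolution (square pixels assumed).
#'
#' @param geometry A [screen_geometry()].
#' @return Pixel pitch in cm.
#' @export
cm_per_pixel <- function(geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  diag_cm <- geometry$diagonal_inches * 2.54
  width_cm <- diag_cm * geometry$aspect_w /
    sqrt(geometry$aspect_w^2 + geometry$aspect_h^2)
  width_cm / geometry$res_x
}

#' Convert a radial pixel offset to degrees of visual angle
#'
#' @param offset_px Radial distance from the screen centre, in pixels
#'   (vectorised, must be non-negative).
#' @param geometry A [screen_geometry()].
#' @return Visual angle in degrees.
#' @seealso [degrees_to_pixels()] for the exact inverse.
#' @export
pixels_to_degrees <- function(offset_px, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(offset_px < 0, na.rm = TRUE)) {
    stop("offset_px must be non-negative")
  }
  atan(offset_px * cm_per_pixel(geometry) / geometry$viewing_distance_cm) *
    180 / pi
}

#' Convert degrees of visual angle to a radial pixel offset
#'
#' Exact inverse of [pixels_to_degrees()].
#'
#' @param angle_deg Visual angle in degrees, in `[0, 90)` (vectorised).
#' @param geometry A [screen_geometry()].
#' @return Radial distance from the screen centre, in pixels.
#' @export
degrees_to_pixels <- function(angle_deg, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(angle_deg < 0 | angle_deg >= 90, na.rm = TRUE)) {
    stop("angle_deg must lie in [0, 90)")
  }
  tan(angle_deg * pi / 180) * geometry$viewing_distance_cm /
    cm_per_pixel(geometry)
}

#' Screen centre in pixel coordinates
#'
#' Origin is the top-left corner with y increasing downward.
#'
#' @param geometry A [screen_geometry()].
#' @return Numeric vector `c(x, y)` in pixels.
#' @export
screen_center <- function(geometry = screen_geometry()) {
  c(x = geometry$res_x / 2, y = geometry$res_y / 2)
}

#' Angular distance between two on-screen gaze points
#'
#' The angle between the two eye-to-point rays, treating the eye as sitting
#' on the normal through the screen centre at the viewing distance.
#' Vectorised over aligned coordinate vectors.
#'
#' @param x1,y1,x2,y2 Pixel coordinates (origin top-left).
#' @param geometry A [screen_geometry()].
#' @return Angular separation in degrees.
#' @export
angular_distance_deg <- function(x1, y1, x2, y2,
                                 geometry = screen_geometry()) {
  cpp <- cm_per_pixel(geometry)
  ctr <- screen_center(geometry)
  d <- geometry$viewing_distance_cm
  ax <- (x1 - ctr[["x"]]) * cpp
  ay <- (y1 - ctr[["y"]]) * cpp
  bx <- (x2 - ctr[["x"]]) * cpp
  by <- (y2 - ctr[["y"]]) * cpp
  dot <- ax * bx + ay * by + d * d
  # cross product of (ax, ay, d) and (bx, by, d)
  cx <- ay * d - d * by
  cy <- d * bx - ax * d
  cz <- ax * by - ay * bx
  atan2(sqrt(cx^2 + cy^2 + cz^2), dot) * 180 / pi
}
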