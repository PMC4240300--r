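#' Viewing geometry for stimulus rendering
#'
#' Bundles the physical viewing distance and the pixel pitch of the display
#' so that sizes can be converted between millimetres, degrees of visual
#' angle and pixels. The canonical setup presents stimuli at 50 cm on a
#' display with 0.25 mm pixels.
#'
#' @param distance_mm Viewing distance in millimetres (default 500).
#' @param pixel_pitch_mm Physical size of one pixel in millimetres
#'   (default 0.25).
#' @return An object of class `viewing_geometry`.
#' @examples
#' geom <- viewing_geometry()
#' mm_to_deg(10.5, geom$distance_mm) # ~1.20 degrees
#' @export
viewing_geometry <- function(distance_mm = 500, pixel_pitch_mm = 0.25) {
  if (!is.numeric(distance_mm) || length(distance_mm) != 1L ||
      !is.finite(distance_mm) || distance_mm <= 0) {
    stop("invalid geometry: distance_mm must be a positive length",
         call. = FALSE)
  }
  if (!is.numeric(pixel_pitch_mm) || length(pixel_pitch_mm) != 1L ||
      !is.finite(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    stop("invalid geometry: pixel_pitch_mm must be a positive length",
         call. = FALSE)
  }
  structure(
    list(distance_mm = distance_mm, pixel_pitch_mm = pixel_pitch_mm),
    class = "viewing_geometry"
  )
}

#' Convert a physical size to degrees of visual angle
#'
#' Uses the exact trigonometric relation
#' \deqn{\theta = 2 \arctan\left(\frac{s}{2d}\right)}
#' for a size \eqn{s} viewed frontoparallel at distance \eqn{d}. At 50 cm a
#' 10.5 mm letter subtends 1.20 degrees.
#'
#' @param size_mm Size in millimetres (non-negative).
#' @param distance_mm Viewing distance in millimetres (positive).
#' @return Visual angle in degrees.
#' @seealso [deg_to_mm()] for the inverse.
#' @export
mm_to_deg <- function(size_mm, distance_mm) {
  if (!is.numeric(distance_mm) || any(!is.finite(distance_mm)) ||
      any(distance_mm <= 0)) {
    stop("invalid geometry: distance_mm must be > 0", call. = FALSE)
  }
  if (!is.numeric(size_mm) || any(!is.finite(size_mm)) || any(size_mm < 0)) {
    stop("invalid geometry: size_mm must be >= 0", call. = FALSE)
  }
  2 * atan(size_mm / (2 * distance_mm)) * 180 / pi
}

#' Convert degrees of visual angle to a physical size
#'
#' Exact inverse of [mm_to_deg()]: \eqn{s = 2 d \tan(\theta / 2)}.
#'
#' @param angle_deg Visual angle in degrees, in `[0, 180)`.
#' @param distance_mm Viewing distance in millimetres (positive).
#' @return Size in millimetres.
#' @export
deg_to_mm <- function(angle_deg, distance_mm) {
  if (!is.numeric(distance_mm) || any(!is.finite(distance_mm)) ||
      any(distance_mm <= 0)) {
    stop("invalid geometry: distance_mm must be > 0", call. = FALSE)
  }
  if (!is.numeric(angle_deg) || any(!is.finite(angle_deg)) ||
      any(angle_deg < 0)) {
    stop("invalid geometry: angle_deg must be >= 0", call. = FALSE)
  }
  if (any(angle_deg >= 180)) {
    stop("invalid geometry: angle_deg must be < 180", call. = FALSE)
  }
  2 * distance_mm * tan(angle_deg * pi / 180 / 2)
}

#' Convert degrees of visual angle to whole pixels
#'
#' @param angle_deg Visual angle in degrees.
#' @param geometry A [viewing_geometry()] object.
#' @return Integer number of pixels (rounded).
#' @export
deg_to_px <- function(angle_deg, geometry) {
  stopifnot(inherits(geometry, "viewing_geometry"))
  as.integer(round(deg_to_mm(angle_deg, geometry$distance_mm) /
                     geometry$pixel_pitch_mm))
}
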