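#' Screen and viewing geometry
#'
#' Describes the monitor and viewing distance used to convert pixel
#' displacements on screen into visual angles. Defaults correspond to a
#' 22-inch 5:4 TFT panel at 1280 x 1024 viewed from 650 mm, a typical
#' setup for a remote desk-mounted eye tracker.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_mm,height_mm physical panel size in millimetres.
#' @param distance_mm eye-to-screen viewing distance in millimetres.
#'
#' @details Pixels are assumed near-square: the horizontal and vertical
#'   pixel pitch must agree within 5%. The conversion uses the mean pitch.
#'
#' @return An object of class `screen_geometry`.
#' @export
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(33.5, geom) # roughly one degree at the default geometry
screen_geometry <- function(width_px = 1280, height_px = 1024,
                            width_mm = 433.6, height_mm = 346.9,
                            distance_mm = 650) {
  vals <- c(width_px = width_px, height_px = height_px,
            width_mm = width_mm, height_mm = height_mm,
            distance_mm = distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be positive and finite")
  }
  pitch_x <- width_mm / width_px
  pitch_y <- height_mm / height_px
  if (abs(pitch_x - pitch_y) / pitch_x > 0.05) {
    stop("pixel pitch differs by more than 5% between axes; pixels must be near-square")
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_mm = width_mm, height_mm = height_mm,
         distance_mm = distance_mm,
         pitch_mm = (pitch_x + pitch_y) / 2),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("Screen geometry: %d x %d px (%.1f x %.1f mm), distance %.0f mm, pitch %.4f mm/px\n",
              x$width_px, x$height_px, x$width_mm, x$height_mm,
              x$distance_mm, x$pitch_mm))
  invisible(x)
}

#' Convert between on-screen pixels and visual degrees
#'
#' `px_to_deg()` maps a pixel displacement to the visual angle it subtends,
#' `deg_to_px()` is its inverse. The angle of a displacement of `s` mm at
#' distance `D` is `2 * atan(s / (2 * D))`.
#'
#' @param px,deg displacement in pixels / degrees (vectorised).
#' @param geometry a [screen_geometry()] object.
#' @return numeric vector of degrees / pixels.
#' @export
px_to_deg <- function(px, geometry) {
  2 * atan(px * geometry$pitch_mm / (2 * geometry$distance_mm)) * 180 / pi
}

#' @rdname px_to_deg
#' @export
deg_to_px <- function(deg, geometry) {
  2 * geometry$distance_mm * tan(deg * pi / 360) / geometry$pitch_mm
}
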