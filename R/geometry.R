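#' Screen geometry for pixel-to-degree conversion
#'
#' Describes the presentation screen and viewing position. Physical size is
#' derived from the diagonal assuming the aspect ratio implied by the pixel
#' grid (square pixels), so a 27-inch 1920x1080 screen is 597.7 x 336.2 mm
#' with a pixel pitch of about 0.311 mm.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_in Physical diagonal in inches.
#' @param distance_mm Viewing distance in millimetres. There is no universal
#'   default for remote trackers; 650 mm is typical for a child seated in
#'   front of a large remote eye tracker and must be set explicitly when it
#'   differs.
#' @return A list of class `screen_geometry` with the resolution, physical
#'   width/height in mm, pixel pitch in mm, and viewing distance.
#' @examples
#' geom <- screen_geometry()
#' geom$pitch_mm
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            diagonal_in = 27, distance_mm = 650) {
  stopifnot(width_px > 0, height_px > 0, diagonal_in > 0, distance_mm > 0)
  diag_mm <- diagonal_in * 25.4
  diag_px <- sqrt(width_px^2 + height_px^2)
  pitch <- diag_mm / diag_px
  structure(
    list(
      width_px = width_px, height_px = height_px,
      width_mm = pitch * width_px, height_mm = pitch * height_px,
      pitch_mm = pitch, distance_mm = distance_mm
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px, %.1f x %.1f mm (pitch %.4f mm), distance %.0f mm\n",
    x$width_px, x$height_px, x$width_mm, x$height_mm, x$pitch_mm, x$distance_mm
  ))
  invisible(x)
}

#' Convert pixel displacements to degrees of visual angle
#'
#' Each axis displacement is converted to an angle via
#' `atan(d_px * pitch_mm / distance_mm)` and the two axis angles are combined
#' as their Euclidean norm. The function is vectorised, odd-symmetric per
#' axis, and monotone in `|d_px|`.
#'
#' @param dx_px,dy_px Displacements in pixels (finite; vectors recycle).
#' @param geometry A [screen_geometry()].
#' @return Visual angle(s) in degrees.
#' @examples
#' px_to_deg(100, 0, screen_geometry(distance_mm = 650))
#' @export
px_to_deg <- function(dx_px, dy_px = 0, geometry = screen_geometry()) {
  ax <- atan(dx_px * geometry$pitch_mm / geometry$distance_mm) * 180 / pi
  ay <- atan(dy_px * geometry$pitch_mm / geometry$distance_mm) * 180 / pi
  sqrt(ax^2 + ay^2)
}

#' Convert a visual angle along one axis to pixels
#'
#' Inverse of the per-axis part of [px_to_deg()]; used by the synthetic
#' generator to place fixation targets at known angular separations.
#'
#' @param deg Angle(s) in degrees.
#' @param geometry A [screen_geometry()].
#' @return Displacement in pixels.
#' @export
deg_to_px <- function(deg, geometry = screen_geometry()) {
  tan(deg * pi / 180) * geometry$distance_mm / geometry$pitch_mm
}
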