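# Scene-camera pinhole model: the head-camera frame spans a known field of
# view (default 95 x 63 deg over 1920 x 1080 px); pixel coordinates map to
# visual angles through atan about the frame centre.

#' Convert scene-camera pixels to visual angles (and back)
#'
#' @param px,py pixel coordinates.
#' @param h,v angles in degrees.
#' @param frame_px frame size c(width, height) in px.
#' @param fov_deg field of view c(horizontal, vertical) in degrees.
#' @return `px_to_deg`: data.frame with `h`, `v` in degrees;
#'   `deg_to_px`: data.frame with `px`, `py`.
#' @export
px_to_deg <- function(px, py, frame_px = c(1920, 1080), fov_deg = c(95, 63)) {
  fx <- (frame_px[1] / 2) / tan(fov_deg[1] / 2 * pi / 180)
  fy <- (frame_px[2] / 2) / tan(fov_deg[2] / 2 * pi / 180)
  data.frame(h = atan((px - frame_px[1] / 2) / fx) * 180 / pi,
             v = atan((py - frame_px[2] / 2) / fy) * 180 / pi)
}

#' @rdname px_to_deg
#' @export
deg_to_px <- function(h, v, frame_px = c(1920, 1080), fov_deg = c(95, 63)) {
  fx <- (frame_px[1] / 2) / tan(fov_deg[1] / 2 * pi / 180)
  fy <- (frame_px[2] / 2) / tan(fov_deg[2] / 2 * pi / 180)
  data.frame(px = frame_px[1] / 2 + fx * tan(h * pi / 180),
             py = frame_px[2] / 2 + fy * tan(v * pi / 180))
}

#' Small-angle pixel-to-degree conversion of a margin
#'
#' Linear conversion used for interpreting pixel margins as visual angle:
#' `margin_px * fov / width`. A 40-px AOI enlargement corresponds to about
#' 2 degrees under the default scene-camera model.
#'
#' @param margin_px margin in pixels.
#' @param frame_px frame width in px.
#' @param fov_deg horizontal field of view in degrees.
#' @export
px_margin_to_deg <- function(margin_px, frame_px = 1920, fov_deg = 95) {
  margin_px * fov_deg / frame_px
}

#' Path length corresponding to an inter-microphone delay
#'
#' Converts a cross-correlation delay threshold into the acoustic path-length
#' difference it represents (delay times the speed of sound). The 0.8-ms
#' in-ear gate corresponds to roughly 30 cm.
#'
#' @param delay_s delay in seconds.
#' @param speed_of_sound m/s.
#' @return distance in meters.
#' @export
delay_to_distance <- function(delay_s, speed_of_sound = 343) {
  delay_s * speed_of_sound
}
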