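#' Screen geometry
#'
#' Describes the flat projection screen used in the experiments. The defaults
#' correspond to a 120 x 90 cm screen viewed from 70 cm at 1152 x 864 px and
#' 120 Hz, which subtends roughly 81 x 65 degrees of visual angle.
#'
#' @param width_cm,height_cm Physical screen size in cm.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @param resolution_px Integer pair, horizontal x vertical pixels.
#' @param refresh_hz Refresh rate in Hz.
#'
#' @return A `screen_geometry` list with the fields above plus
#'   `frame_duration_ms = 1000 / refresh_hz`.
#' @examples
#' geom <- screen_geometry()
#' 2 * cm_to_deg(geom$width_cm / 2, geom$viewing_distance_cm) # ~81 deg
#' @export
screen_geometry <- function(width_cm = 120, height_cm = 90,
                            viewing_distance_cm = 70,
                            resolution_px = c(1152L, 864L),
                            refresh_hz = 120) {
  vals <- c(width_cm, height_cm, viewing_distance_cm, resolution_px, refresh_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("screen_geometry: all dimensions must be positive and finite",
         call. = FALSE)
  }
  structure(
    list(width_cm = width_cm, height_cm = height_cm,
         viewing_distance_cm = viewing_distance_cm,
         resolution_px = as.integer(resolution_px),
         refresh_hz = refresh_hz,
         frame_duration_ms = 1000 / refresh_hz),
    class = "screen_geometry")
}

#' Convert a flat-screen offset in cm to degrees of visual angle
#'
#' Uses per-point arctangent geometry (not a small-angle approximation), so
#' that half the 120-cm screen at 70 cm maps to about 40.6 degrees and the
#' full width to about 81 degrees.
#'
#' @param offset_cm Signed offset from the screen point nearest the eye, cm.
#' @param distance_cm Viewing distance, cm; must be positive.
#' @return Signed visual angle in degrees; odd in `offset_cm`.
#' @examples
#' cm_to_deg(70, 70) # 45 degrees
#' @export
cm_to_deg <- function(offset_cm, distance_cm) {
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("cm_to_deg: viewing distance must be positive", call. = FALSE)
  }
  atan(offset_cm / distance_cm) * 180 / pi
}

#' Inverse of [cm_to_deg()]
#'
#' @param angle_deg Signed visual angle in degrees (|angle| < 90).
#' @param distance_cm Viewing distance, cm; must be positive.
#' @return Signed screen offset in cm.
#' @export
deg_to_cm <- function(angle_deg, distance_cm) {
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("deg_to_cm: viewing distance must be positive", call. = FALSE)
  }
  if (any(abs(angle_deg) >= 90)) {
    stop("deg_to_cm: angle must lie strictly inside (-90, 90) degrees",
         call. = FALSE)
  }
  tan(angle_deg * pi / 180) * distance_cm
}

#' Map a screen-axis value onto the eccentricity axis
#'
#' The screen axis is signed positive rightward from screen centre. The
#' eccentricity axis is signed positive *away from the screen centre within
#' the stimulus hemifield*, which lets left- and right-hemifield trials be
#' pooled. The mapping is the identity for right-hemifield stimuli and a sign
#' flip for left-hemifield stimuli; applying it twice recovers the input.
#'
#' @param value_screen_deg Value(s) on the screen axis, degrees.
#' @param hemifield `"left"` or `"right"` (vectorised).
#' @return Value(s) on the eccentricity axis, degrees.
#' @export
to_eccentricity_axis <- function(value_screen_deg, hemifield) {
  hemifield <- match_hemifield(hemifield)
  ifelse(hemifield == "left", -1, 1) * value_screen_deg
}

#' Retinal position of a stimulus, signed toward greater eccentricity
#'
#' Computes the stimulus position relative to the fovea (stimulus minus eye,
#' both on the screen axis) and re-signs it so that positive means *more
#' eccentric within the stimulus hemifield*. During rightward pursuit a flash
#' at +7.5 deg seen when the eye is at +2 deg is 5.5 deg eccentric on the
#' retina.
#'
#' @param stimulus_screen_deg Stimulus position on the screen axis, degrees.
#' @param eye_screen_deg Eye position on the screen axis, degrees.
#' @param hemifield Stimulus hemifield, `"left"` or `"right"` (vectorised).
#' @return Signed retinal eccentricity in degrees.
#' @export
retinal_position <- function(stimulus_screen_deg, eye_screen_deg, hemifield) {
  to_eccentricity_axis(stimulus_screen_deg - eye_screen_deg, hemifield)
}

match_hemifield <- function(hemifield) {
  hemifield <- as.character(hemifield)
  if (!all(hemifield %in% c("left", "right"))) {
    stop("hemifield must be 'left' or 'right'", call. = FALSE)
  }
  hemifield
}
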