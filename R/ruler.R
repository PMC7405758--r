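#' Ruler line positions
#'
#' The report ruler spans -20 to +20 deg with vertical lines every 0.8 deg
#' (51 lines); in half the trials the whole ruler is shifted by +0.4 deg so
#' that averaging the two halves doubles the effective spatial resolution.
#'
#' @param shifted Logical; apply the 0.4-deg global shift.
#' @return Numeric vector of 51 line positions, screen axis, degrees.
#' @export
ruler_lines <- function(shifted = FALSE) {
  seq(-20, 20, by = 0.8) + ifelse(shifted, 0.4, 0)
}

# Fresh random injection of the 51 lines into the labels 00..99, regenerated
# deterministically from the per-trial map seed.
ruler_label_map <- function(map_seed) {
  withr::with_seed(as.integer(map_seed %% 2147483647L),
                   sample(0:99, length(ruler_lines())))
}

#' Encode a perceived position as a ruler-label report
#'
#' The report is the label of the ruler line nearest the perceived position.
#' Labels are a fresh random assignment of the numbers 00-99 to the 51 lines
#' on every trial (regenerated from `map_seed`). Positions beyond the ruler
#' span are clamped to the end line and flagged.
#'
#' @param position_deg Perceived position, screen axis, degrees.
#' @param map_seed Integer seed of the trial's label assignment.
#' @param shifted Logical; ruler shifted by 0.4 deg.
#' @return List: `label` (integer 0-99), `clamped` (logical).
#' @export
encode_ruler <- function(position_deg, map_seed, shifted = FALSE) {
  lines <- ruler_lines(shifted)
  clamped <- position_deg < min(lines) - 0.4 | position_deg > max(lines) + 0.4
  idx <- which.min(abs(lines - position_deg))
  map <- ruler_label_map(map_seed)
  list(label = map[idx], clamped = clamped)
}

#' Decode a ruler-label report back to a line position
#'
#' Regenerates the trial's label assignment from `map_seed` and returns the
#' position of the line that carried the reported label. Decoding an encoded
#' position recovers the quantised line position exactly.
#'
#' @param label Reported label (integer 0-99).
#' @param map_seed Integer seed of the trial's label assignment.
#' @param shifted Logical; ruler shifted by 0.4 deg.
#' @return Line position on the screen axis, degrees.
#' @export
decode_ruler <- function(label, map_seed, shifted = FALSE) {
  map <- ruler_label_map(map_seed)
  idx <- match(label, map)
  if (is.na(idx)) {
    stop("decode_ruler: label ", label, " was not assigned to any line",
         call. = FALSE)
  }
  ruler_lines(shifted)[idx]
}
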