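# Savitzky-Golay smoothed differentiation (5-sample window) applied
# segment-wise over the valid runs; invalid samples and runs too short for
# the window get NA velocity.
velocity_trace <- function(trace) {
  n <- nrow(trace)
  v <- rep(NA_real_, n)
  dt <- stats::median(diff(trace$t_ms)) / 1000
  r <- rle(trace$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < 5) next
    seg <- starts[i]:ends[i]
    v[seg] <- signal::sgolayfilt(trace$x_deg[seg], p = 2, n = 5, m = 1,
                                 ts = dt)
  }
  v
}

merge_intervals <- function(onsets, offsets, gap_ms) {
  if (length(onsets) == 0) return(list(onset = numeric(), offset = numeric()))
  ord <- order(onsets)
  onsets <- onsets[ord]; offsets <- offsets[ord]
  out_on <- onsets[1]; out_off <- offsets[1]
  for (i in seq_along(onsets)[-1]) {
    if (onsets[i] - out_off[length(out_off)] < gap_ms) {
      out_off[length(out_off)] <- max(out_off[length(out_off)], offsets[i])
    } else {
      out_on <- c(out_on, onsets[i])
      out_off <- c(out_off, offsets[i])
    }
  }
  list(onset = out_on, offset = out_off)
}

#' Detect saccades in an eye trace
#'
#' Flags contiguous runs where the smoothed eye velocity deviates from the
#' expected pursuit velocity by more than `velocity_threshold` for at least
#' `min_duration_ms`; runs separated by less than 20 ms are merged.
#' Velocity is estimated by Savitzky-Golay smoothed differentiation over a
#' 5-sample (8-ms aperture) window, so the threshold is applied to velocity
#' *relative to the pursuit baseline*, and clean pursuit at 10 deg/s yields
#' no events.
#'
#' @param trace An [eye_trace()].
#' @param velocity_threshold Threshold in deg/s (default 30).
#' @param min_duration_ms Minimum event duration in ms (default 8).
#' @param expected_velocity Expected eye velocity in deg/s (signed, screen
#'   axis). Default: the nominal target velocity from the trace metadata
#'   (direction sign times target speed), 0 for fixation.
#' @return Tibble of events: `kind = "saccade"`, `onset_ms`, `offset_ms`.
#' @export
detect_saccades <- function(trace, velocity_threshold = 30,
                            min_duration_ms = 8, expected_velocity = NULL) {
  if (sum(trace$valid) < 2) {
    warning("detect_saccades: all-invalid trace, returning no events",
            call. = FALSE)
    return(empty_events())
  }
  if (is.null(expected_velocity)) {
    meta <- trace_meta(trace)
    expected_velocity <- if (!is.null(meta$pursuit_direction) &&
                             meta$pursuit_direction != "none") {
      direction_sign(meta$pursuit_direction) *
        (meta$target_speed %||% 10)
    } else 0
  }
  v <- velocity_trace(trace)
  excess <- !is.na(v) & abs(v - expected_velocity) > velocity_threshold
  dt <- stats::median(diff(trace$t_ms))
  r <- rle(excess)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * dt >= min_duration_ms
  if (!any(keep)) return(empty_events())
  merged <- merge_intervals(trace$t_ms[starts[keep]],
                            trace$t_ms[ends[keep]], gap_ms = 20)
  tibble::tibble(kind = "saccade", onset_ms = merged$onset,
                 offset_ms = merged$offset)
}

#' Detect blinks in an eye trace
#'
#' Maximal runs of invalid samples lasting at least 20 ms, padded by 20 ms on
#' each side (tracker signal loss starts before and ends after the true lid
#' closure); padded intervals that touch are merged.
#'
#' @param trace An [eye_trace()].
#' @return Tibble of events: `kind = "blink"`, `onset_ms`, `offset_ms`.
#' @export
detect_blinks <- function(trace) {
  dt <- stats::median(diff(trace$t_ms))
  r <- rle(!trace$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * dt >= 20
  if (!any(keep)) return(empty_events())
  merged <- merge_intervals(trace$t_ms[starts[keep]] - 20,
                            trace$t_ms[ends[keep]] + 20, gap_ms = 0)
  tibble::tibble(kind = "blink",
                 onset_ms = pmax(merged$onset, min(trace$t_ms)),
                 offset_ms = pmin(merged$offset, max(trace$t_ms)))
}

#' Pursuit gain around a flash
#'
#' Robust (20%-trimmed) mean of the per-sample eye velocity in the window
#' from 100 ms before to 100 ms after the flash, divided by the signed
#' target velocity. Samples inside detected saccades or blinks are masked;
#' if more than half the window is masked the gain is undefined.
#'
#' @param trace An [eye_trace()].
#' @param flash_ms Flash time in ms; the window must lie inside the trace.
#' @param target_velocity Signed target velocity on the screen axis, deg/s
#'   (e.g. -10 for leftward pursuit at 10 deg/s); must be nonzero.
#' @return Dimensionless gain.
#' @export
compute_gain <- function(trace, flash_ms, target_velocity) {
  if (target_velocity == 0) {
    stop("compute_gain: target velocity must be nonzero", call. = FALSE)
  }
  lo <- flash_ms - 100; hi <- flash_ms + 100
  if (lo < min(trace$t_ms) || hi > max(trace$t_ms)) {
    stop("compute_gain: the gain window extends beyond the trace",
         call. = FALSE)
  }
  v <- velocity_trace(trace)
  in_win <- trace$t_ms >= lo & trace$t_ms <= hi
  ev <- dplyr::bind_rows(detect_saccades(trace), detect_blinks(trace))
  masked <- rep(FALSE, nrow(trace))
  for (i in seq_len(nrow(ev))) {
    masked <- masked | (trace$t_ms >= ev$onset_ms[i] &
                          trace$t_ms <= ev$offset_ms[i])
  }
  use <- in_win & !masked & !is.na(v)
  if (sum(use) < 0.5 * sum(in_win)) {
    stop("compute_gain: more than half of the gain window is masked",
         call. = FALSE)
  }
  mean(v[use], trim = 0.2) / target_velocity
}

#' Width of the saccade/blink exclusion span
#'
#' Union of the two per-stimulus windows (each flash +/- `event_window_ms`):
#' 400 ms at |SOA| = 200 ms, 200 ms for simultaneous presentation.
#'
#' @param soa_ms Signed SOA in ms.
#' @param event_window_ms Half-width of each stimulus window, ms.
#' @return Span in ms.
#' @export
exclusion_window_span <- function(soa_ms, event_window_ms = 100) {
  pmin(4 * event_window_ms, 2 * event_window_ms + abs(soa_ms))
}

#' Apply the trial-exclusion rules
#'
#' A trial is excluded if (i) a frame drop was logged, (ii) the eye deviated
#' more than `deviation_limit` (2 deg) from the instantaneous pursuit-target
#' or fixation-point position at any time from 50 ms before to 50 ms after
#' the reference flash, or (iii) a detected saccade or blink overlaps either
#' stimulus window (flash +/- 100 ms; together a 400-ms span at |SOA| =
#' 200 ms). Trials whose trace is missing are flagged invalid and reported,
#' never silently dropped.
#'
#' @param trials Trial tibble with condition columns and `trace_id`
#'   (optionally `frame_drop`).
#' @param traces Named list of [eye_trace()] objects keyed by `trace_id`.
#' @param deviation_limit Deviation limit, deg (default 2).
#' @param deviation_window_ms Half-width of the deviation window, ms (50).
#' @param event_window_ms Half-width of each stimulus window, ms (100).
#' @param velocity_threshold,min_duration_ms Saccade-detection settings.
#' @param speed Pursuit target speed, deg/s.
#' @return `trials` with logical columns `frame_drop`, `deviation_exceeded`,
#'   `saccade_blink_near_flash`, `missing_trace`, and `qc_valid`.
#' @export
exclude_trials <- function(trials, traces, deviation_limit = 2,
                           deviation_window_ms = 50, event_window_ms = 100,
                           velocity_threshold = 30, min_duration_ms = 8,
                           speed = 10) {
  n <- nrow(trials)
  if (!"frame_drop" %in% names(trials)) trials$frame_drop <- FALSE
  deviation <- logical(n); near_flash <- logical(n); missing <- logical(n)
  for (i in seq_len(n)) {
    tr <- traces[[trials$trace_id[i]]]
    if (is.null(tr)) {
      missing[i] <- TRUE
      next
    }
    ft <- flash_times(trials$task[i], trials$soa_ms[i])
    anchor <- if (is.na(ft$reference_ms)) ft$target_ms else ft$reference_ms
    in_dev <- tr$t_ms >= anchor - deviation_window_ms &
      tr$t_ms <= anchor + deviation_window_ms
    tpos <- target_position(tr$t_ms, trials$task[i],
                            trials$pursuit_direction[i], speed)
    deviation[i] <- any(in_dev & tr$valid &
                          abs(tr$x_deg - tpos) > deviation_limit,
                        na.rm = TRUE)
    exp_v <- direction_sign(trials$pursuit_direction[i]) * speed
    ev <- dplyr::bind_rows(
      detect_saccades(tr, velocity_threshold, min_duration_ms,
                      expected_velocity = exp_v),
      detect_blinks(tr))
    stim_times <- c(ft$reference_ms, ft$target_ms)
    stim_times <- stim_times[!is.na(stim_times)]
    if (nrow(ev) > 0) {
      for (st in stim_times) {
        near_flash[i] <- near_flash[i] ||
          any(ev$onset_ms <= st + event_window_ms &
                ev$offset_ms >= st - event_window_ms)
      }
    }
  }
  if (any(missing)) {
    warning(sum(missing), " trial(s) had no matching trace and were ",
            "flagged invalid", call. = FALSE)
  }
  trials$deviation_exceeded <- deviation
  trials$saccade_blink_near_flash <- near_flash
  trials$missing_trace <- missing
  trials$qc_valid <- !trials$frame_drop & !deviation & !near_flash & !missing
  trials
}

#' Per-condition exclusion report
#'
#' Counts of trials per exclusion reason and condition cell.
#'
#' @param trials Output of [exclude_trials()].
#' @return Tibble with one row per condition cell.
#' @export
qc_report <- function(trials) {
  keys <- intersect(c("subject", "task", "phase", "pursuit_direction",
                      "placement", "soa_ms"), names(trials))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_frame_drop = sum(.data$frame_drop),
      n_deviation = sum(.data$deviation_exceeded),
      n_saccade_blink = sum(.data$saccade_blink_near_flash),
      n_missing_trace = sum(.data$missing_trace),
      n_valid = sum(.data$qc_valid),
      .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
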