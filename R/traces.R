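#' Construct an eye trace
#'
#' A gaze time series sampled at 500 Hz (2-ms spacing): time, horizontal
#' position on the screen axis, and a per-sample validity flag. Annotated
#' events (saccades, blinks) and trace metadata travel as attributes.
#'
#' @param t_ms Strictly increasing sample times, ms.
#' @param x_deg Gaze position on the screen axis, degrees (NA while invalid).
#' @param valid Logical validity per sample.
#' @param events Tibble with columns `kind` ("saccade"/"blink"), `onset_ms`,
#'   `offset_ms`; must lie within the trace span.
#' @param meta List of metadata (task, pursuit direction, trial gain, ...).
#' @return An `eye_trace` tibble.
#' @export
eye_trace <- function(t_ms, x_deg, valid = rep(TRUE, length(t_ms)),
                      events = empty_events(), meta = list()) {
  if (length(t_ms) < 2 || any(diff(t_ms) <= 0)) {
    stop("eye_trace: t_ms must be strictly increasing with >= 2 samples",
         call. = FALSE)
  }
  if (nrow(events) > 0 &&
      (any(events$onset_ms < min(t_ms)) || any(events$offset_ms > max(t_ms)))) {
    stop("eye_trace: events must lie within the trace span", call. = FALSE)
  }
  out <- tibble::tibble(t_ms = t_ms, x_deg = x_deg, valid = valid)
  attr(out, "events") <- events
  attr(out, "meta") <- meta
  class(out) <- c("eye_trace", class(out))
  out
}

empty_events <- function() {
  tibble::tibble(kind = character(), onset_ms = numeric(),
                 offset_ms = numeric())
}

#' Ground-truth events of a trace
#' @param trace An `eye_trace`.
#' @return Tibble of annotated events.
#' @export
trace_events <- function(trace) {
  ev <- attr(trace, "events")
  if (is.null(ev)) empty_events() else ev
}

#' Metadata of a trace
#' @param trace An `eye_trace`.
#' @return List of metadata.
#' @export
trace_meta <- function(trace) {
  m <- attr(trace, "meta")
  if (is.null(m)) list() else m
}

#' Nominal pursuit-target (or fixation-point) position over time
#'
#' The pursuit target crosses the screen centre at 1250 ms moving at `speed`
#' deg/s in the pursuit direction; the fixation point sits at 0 deg.
#'
#' @param t_ms Times in ms.
#' @param task Task name.
#' @param pursuit_direction `"leftward"`, `"rightward"`, or `"none"`.
#' @param speed Target speed, deg/s.
#' @return Target position on the screen axis, degrees.
#' @export
target_position <- function(t_ms, task, pursuit_direction, speed = 10) {
  if (task == "fixation_relative" || pursuit_direction == "none") {
    return(rep(0, length(t_ms)))
  }
  direction_sign(pursuit_direction) * speed * (t_ms - REFERENCE_FLASH_MS) / 1000
}

#' Simulate a 500-Hz eye trace for one trial
#'
#' Fixation trials hold gaze at the screen centre for 1750 ms; pursuit trials
#' last 2500 ms, with the eye tracking the target at `speed * gain` deg/s
#' (trial gain drawn from the observer's gain distribution) and anchored to
#' the centre crossing at 1250 ms. White positional noise is added
#' throughout. Catch-up saccades are injected as instantaneous position steps
#' (amplitude 0.8-2.5 deg, Poisson arrivals at the observer's rate, 200-ms
#' refractory period, biased in the pursuit direction) and blinks as 60-200
#' ms runs of invalid samples; both are annotated as ground-truth events.
#'
#' @param cond A [condition()] row.
#' @param observer An `observer_params` object.
#' @param seed Integer seed; the trace is deterministic given the seed.
#' @param speed Pursuit target speed, deg/s.
#' @return An [eye_trace()].
#' @export
simulate_eye_trace <- function(cond, observer, seed = 1, speed = 10) {
  withr::with_seed(as.integer(seed %% 2147483647L), {
    duration <- trial_duration_ms(cond$task)
    t_ms <- seq(0, duration - 2, by = 2)
    n <- length(t_ms)
    pursuit <- cond$task != "fixation_relative"
    gain <- if (pursuit) {
      min(1.5, max(0.5, stats::rnorm(1, observer$pursuit_gain,
                                     observer$gain_sd)))
    } else NA_real_
    x <- if (pursuit) {
      direction_sign(cond$pursuit_direction) * speed * gain *
        (t_ms - REFERENCE_FLASH_MS) / 1000
    } else {
      rep(0, n)
    }
    x <- x + stats::rnorm(n, 0, observer$trace_noise_deg)
    events <- empty_events()

    # catch-up saccades: instantaneous steps with a refractory period
    n_sac <- stats::rpois(1, observer$saccade_rate_hz * duration / 1000)
    if (n_sac > 0) {
      onsets <- sort(stats::runif(n_sac, 100, duration - 100))
      keep <- c(TRUE, diff(onsets) >= 200)
      onsets <- onsets[keep]
      for (on in onsets) {
        amp <- stats::runif(1, 0.8, 2.5)
        sgn <- if (pursuit) {
          ifelse(stats::runif(1) < 0.8,
                 direction_sign(cond$pursuit_direction),
                 -direction_sign(cond$pursuit_direction))
        } else {
          sample(c(-1, 1), 1)
        }
        x[t_ms >= on] <- x[t_ms >= on] + sgn * amp
        events <- dplyr::bind_rows(events,
          tibble::tibble(kind = "saccade", onset_ms = on, offset_ms = on + 2))
      }
    }

    valid <- rep(TRUE, n)
    if (stats::runif(1) < observer$blink_prob) {
      b_on <- stats::runif(1, 100, duration - 300)
      b_dur <- stats::runif(1, 60, 200)
      bad <- t_ms >= b_on & t_ms <= b_on + b_dur
      valid[bad] <- FALSE
      x[bad] <- NA_real_
      events <- dplyr::bind_rows(events,
        tibble::tibble(kind = "blink", onset_ms = b_on,
                       offset_ms = b_on + b_dur))
    }

    eye_trace(t_ms, x, valid, events,
              meta = list(task = cond$task,
                          pursuit_direction = cond$pursuit_direction,
                          gain = gain, target_speed = speed, seed = seed))
  })
}

# Deterministic per-trial seed streams: successive Lehmer-style folding of the
# master seed with integer parts, kept strictly below 2^31.
derive_seed <- function(master, ...) {
  x <- as.numeric(master) %% 2147483647
  for (part in c(...)) {
    x <- (x * 48271 + as.numeric(part) + 1) %% 2147483647
  }
  as.integer(x)
}
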