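#' Lapse-augmented cumulative-Gaussian psychometric function
#'
#' `psi(x) = guess + (1 - guess - lapse) * Phi((x - pse) / sigma)`: the
#' probability of judging the target more eccentric than the reference at a
#' target offset `x` on the eccentricity axis.
#'
#' @param x Offset(s) on the eccentricity axis, degrees.
#' @param pse Point of subjective equality, degrees.
#' @param sigma Spread, degrees (> 0).
#' @param guess,lapse Lower/upper asymptote slack, probabilities.
#' @return Probability of a "target more eccentric" judgment.
#' @export
psychometric_prob <- function(x, pse, sigma, guess = 0, lapse = 0) {
  stopifnot(sigma > 0)
  guess + (1 - guess - lapse) * stats::pnorm((x - pse) / sigma)
}

#' Simulate one relative-localization trial
#'
#' Draws the observer's binary judgment from the lapse-augmented cumulative
#' Gaussian centred on the observer's ground-truth PSE ([true_pse()]) for the
#' condition, then re-expresses the judgment as the raw response key: "was
#' the target perceived more to the right?" (`response_right`), which equals
#' the more-eccentric judgment in the right hemifield and its negation in the
#' left.
#'
#' @param observer An `observer_params`.
#' @param cond A [condition()] row for a relative task.
#' @param offset_deg Target offset from the reference, screen axis, degrees.
#' @param seed Integer seed.
#' @return One-row tibble: condition columns, `offset_deg`, `response_right`.
#' @export
simulate_relative_trial <- function(observer, cond, offset_deg, seed = 1) {
  p <- relative_response_prob(observer, cond, offset_deg)
  judged_ecc <- withr::with_seed(as.integer(seed %% 2147483647L),
                                 stats::rbinom(1, 1, p))
  resp_right <- ifelse(cond$hemifield == "right", judged_ecc, 1L - judged_ecc)
  dplyr::bind_cols(cond,
                   tibble::tibble(offset_deg = offset_deg,
                                  response_right = as.integer(resp_right)))
}

# Analytic probability of a "target more eccentric" judgment for one trial.
relative_response_prob <- function(observer, cond, offset_deg) {
  offset_ecc <- to_eccentricity_axis(offset_deg, cond$hemifield)
  psychometric_prob(offset_ecc, true_pse(observer, cond),
                    observer$sigma_deg, observer$guess, observer$lapse)
}

# Vectorised relative-trial simulation over a schedule (one RNG stream).
simulate_relative_block <- function(observer, schedule, seed = 1) {
  cond_cols <- c("task", "phase", "hemifield", "pursuit_direction",
                 "placement", "soa_ms")
  cells <- dplyr::distinct(schedule[, cond_cols])
  cells$.pse <- purrr::map_dbl(seq_len(nrow(cells)),
                               function(i) true_pse(observer, cells[i, ]))
  pse <- dplyr::left_join(schedule, cells, by = cond_cols)$.pse
  offset_ecc <- to_eccentricity_axis(schedule$offset_deg, schedule$hemifield)
  p <- psychometric_prob(offset_ecc, pse, observer$sigma_deg,
                         observer$guess, observer$lapse)
  judged <- withr::with_seed(as.integer(seed %% 2147483647L),
                             stats::rbinom(nrow(schedule), 1, p))
  out <- schedule
  out$response_right <- ifelse(out$hemifield == "right", judged, 1L - judged)
  out
}

#' Simulate one absolute-localization (ruler) trial
#'
#' The flash appears at 7.5 deg eccentricity in the hemifield implied by the
#' condition; its retinal eccentricity at flash time follows from the eye
#' position. The perceived position adds the observer's linear eccentricity
#' effect (`intercept + a * retinal eccentricity`, on the eccentricity axis)
#' plus report noise, and is reported as the nearest ruler-line label under a
#' fresh random label assignment ([encode_ruler()]).
#'
#' @param observer An `observer_params`.
#' @param cond A [condition()] row with `task == "pursuit_absolute"`.
#' @param seed Integer seed.
#' @param ruler_shifted Logical; use the 0.4-deg-shifted ruler.
#' @param eye_at_flash_deg Eye position at the flash (screen axis, degrees);
#'   default: the nominal pursuit trajectory at the flash time with a trial
#'   gain drawn from the observer's gain distribution.
#' @param reference_ecc_deg Flash eccentricity, degrees (default 7.5).
#' @param speed Pursuit speed, deg/s.
#' @return One-row tibble: condition columns, `ruler_shifted`, `target_deg`,
#'   `eye_at_flash_deg`, `perceived_deg` (pre-quantisation ground truth),
#'   `reported_label`, `ruler_map_seed`, `clamped`.
#' @export
simulate_absolute_trial <- function(observer, cond, seed = 1,
                                    ruler_shifted = FALSE,
                                    eye_at_flash_deg = NULL,
                                    reference_ecc_deg = 7.5, speed = 10) {
  if (cond$task != "pursuit_absolute") {
    stop("simulate_absolute_trial needs a pursuit_absolute condition",
         call. = FALSE)
  }
  seed <- as.integer(seed %% 2147483647L)
  withr::with_seed(seed, {
    target_deg <- to_eccentricity_axis(reference_ecc_deg, cond$hemifield)
    if (is.null(eye_at_flash_deg)) {
      gain <- min(1.5, max(0.5, stats::rnorm(1, observer$pursuit_gain,
                                             observer$gain_sd)))
      eye_at_flash_deg <- direction_sign(cond$pursuit_direction) * speed *
        gain * cond$soa_ms / 1000
    }
    ecc_ret <- retinal_position(target_deg, eye_at_flash_deg, cond$hemifield)
    a <- if (cond$placement == "ahead") observer$ecc_slope_ahead else
      observer$ecc_slope_behind
    b <- if (cond$placement == "ahead") observer$ecc_intercept_ahead else
      observer$ecc_intercept_behind
    misloc_ecc <- b + a * ecc_ret +
      stats::rnorm(1, 0, observer$ruler_noise_deg)
    perceived_ecc <- to_eccentricity_axis(target_deg, cond$hemifield) +
      misloc_ecc
    perceived_deg <- to_eccentricity_axis(perceived_ecc, cond$hemifield)
    map_seed <- derive_seed(seed, 7919)
    enc <- encode_ruler(perceived_deg, map_seed, ruler_shifted)
    dplyr::bind_cols(cond,
      tibble::tibble(ruler_shifted = ruler_shifted, target_deg = target_deg,
                     eye_at_flash_deg = eye_at_flash_deg,
                     perceived_deg = perceived_deg,
                     reported_label = enc$label,
                     ruler_map_seed = map_seed, clamped = enc$clamped))
  })
}

# Vectorised absolute-trial simulation over a schedule. eye_at_flash_deg may
# contain NAs (nominal trajectory with a drawn trial gain is used instead).
simulate_absolute_block <- function(observer, sched, seed = 1,
                                    eye_at_flash_deg = NULL,
                                    reference_ecc_deg = 7.5, speed = 10) {
  n <- nrow(sched)
  if (is.null(eye_at_flash_deg)) eye_at_flash_deg <- rep(NA_real_, n)
  seed <- as.integer(seed %% 2147483647L)
  withr::with_seed(seed, {
    target_deg <- to_eccentricity_axis(reference_ecc_deg, sched$hemifield)
    gains <- pmin(1.5, pmax(0.5, stats::rnorm(n, observer$pursuit_gain,
                                              observer$gain_sd)))
    nominal <- direction_sign(sched$pursuit_direction) * speed * gains *
      sched$soa_ms / 1000
    eye <- ifelse(is.na(eye_at_flash_deg), nominal, eye_at_flash_deg)
    ecc_ret <- retinal_position(target_deg, eye, sched$hemifield)
    ahead <- sched$placement == "ahead"
    a <- ifelse(ahead, observer$ecc_slope_ahead, observer$ecc_slope_behind)
    b <- ifelse(ahead, observer$ecc_intercept_ahead,
                observer$ecc_intercept_behind)
    misloc <- b + a * ecc_ret + stats::rnorm(n, 0, observer$ruler_noise_deg)
    perceived_ecc <- reference_ecc_deg + misloc
    perceived_deg <- to_eccentricity_axis(perceived_ecc, sched$hemifield)
    map_seeds <- vapply(seq_len(n),
                        function(i) derive_seed(seed, i, 7919), integer(1))
    label <- integer(n); clamped <- logical(n)
    for (i in seq_len(n)) {
      enc <- encode_ruler(perceived_deg[i], map_seeds[i],
                          sched$ruler_shifted[i])
      label[i] <- enc$label; clamped[i] <- enc$clamped
    }
    out <- sched
    out$target_deg <- target_deg
    out$eye_at_flash_deg <- eye
    out$perceived_deg <- perceived_deg
    out$reported_label <- label
    out$ruler_map_seed <- map_seeds
    out$clamped <- clamped
    out
  })
}

#' Decode reported ruler labels in an absolute-trial table
#'
#' Adds a `perceived_deg` column (the decoded, quantised ruler position) to a
#' table of absolute trials carrying `reported_label`, `ruler_map_seed`, and
#' `ruler_shifted`.
#'
#' @param trials Absolute-trial tibble.
#' @return The tibble with `perceived_deg` replaced by the decoded positions.
#' @export
decode_absolute_trials <- function(trials) {
  trials$perceived_deg <- purrr::pmap_dbl(
    trials[, c("reported_label", "ruler_map_seed", "ruler_shifted")],
    function(reported_label, ruler_map_seed, ruler_shifted) {
      decode_ruler(reported_label, ruler_map_seed, ruler_shifted)
    })
  trials
}
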