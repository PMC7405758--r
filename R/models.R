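#' Sign factor for SOA-by-placement shifts
#'
#' During pursuit the eye displaces between the two flashes, and the sign of
#' every induced PSE shift depends jointly on the SOA sign and on whether the
#' flashes are ahead of or behind the pursuit target: positive for
#' (positive SOA, ahead) and (negative SOA, behind), negative for the other
#' two cells, and zero for simultaneous presentation.
#'
#' @param soa_ms Signed stimulus onset asynchrony in ms (vectorised).
#' @param placement `"ahead"` or `"behind"` (vectorised).
#' @return +1, -1, or 0 for `soa_ms == 0`.
#' @export
signed_condition_factor <- function(soa_ms, placement) {
  if (!all(placement %in% c("ahead", "behind"))) {
    stop("placement must be 'ahead' or 'behind'", call. = FALSE)
  }
  s <- sign(soa_ms)
  ifelse(placement == "ahead", s, -s)
}

#' PSE shift compensating the eccentricity effect
#'
#' The eye displacement `speed * |soa| / 1000` between the two flashes changes
#' the target's retinal eccentricity, and absolute mislocalization grows
#' linearly in retinal eccentricity with slope `a`. The PSE shift that cancels
#' this effect is the displacement times `a`, signed by
#' [signed_condition_factor()]. At 10 deg/s and 200 ms this is the familiar
#' `+/- 2 a`: +0.48 deg for `a = 0.24` ahead, -0.52 deg for `a = 0.26` behind
#' (positive SOA).
#'
#' @param a Eccentricity slope (deg mislocalization per deg retinal
#'   eccentricity), dimensionless.
#' @param soa_ms Signed SOA in ms; |soa_ms| <= 500.
#' @param speed Pursuit speed in deg/s (default 10).
#' @param placement `"ahead"` or `"behind"`.
#' @return Signed PSE shift in degrees on the eccentricity axis.
#' @export
compensation_shift <- function(a, soa_ms, speed = 10, placement) {
  if (any(!is.finite(a))) stop("slope a must be finite", call. = FALSE)
  if (any(abs(soa_ms) > 500)) {
    stop("|soa_ms| must be at most 500 ms", call. = FALSE)
  }
  signed_condition_factor(soa_ms, placement) * (speed * abs(soa_ms) / 1000) * a
}

#' Retinal displacement between the two flashes
#'
#' In an eye-centered reference frame the second flash is displaced on the
#' retina by the full eye movement during the inter-stimulus interval:
#' `speed * |soa| / 1000`, i.e. 2 deg at 10 deg/s and 200 ms, signed by
#' [signed_condition_factor()]. `fraction` scales the displacement (e.g. 0.5
#' for a reference frame that compensates half of the eye movement).
#'
#' @param soa_ms Signed SOA in ms.
#' @param speed Pursuit speed in deg/s (default 10).
#' @param placement `"ahead"` or `"behind"`.
#' @param fraction Fraction of the eye displacement expressed in the shift,
#'   in \[-1, 1\]; default 1 (fully eye-centered).
#' @return Signed shift in degrees on the eccentricity axis.
#' @export
retinal_shift <- function(soa_ms, speed = 10, placement, fraction = 1.0) {
  if (any(abs(fraction) > 1)) {
    stop("|fraction| must be at most 1", call. = FALSE)
  }
  signed_condition_factor(soa_ms, placement) * speed * abs(soa_ms) / 1000 *
    fraction
}

#' Predicted pursuit PSE under one of four reference-frame models
#'
#' Model A: relative localization in a screen-/head-centered frame with no
#' eccentricity effect -- the pursuit PSE equals the fixation PSE. Model B:
#' eye-centered frame -- the fixation PSE plus the full retinal displacement
#' ([retinal_shift()]). Model C: screen-centered frame plus the eccentricity
#' effect ([compensation_shift()]). Model D: eye-centered frame plus the
#' eccentricity effect.
#'
#' @param model `"A"`, `"B"`, `"C"`, or `"D"`.
#' @param fixation_pse Fixation PSE for the same SOA, degrees
#'   (eccentricity axis).
#' @param soa_ms Signed SOA in ms.
#' @param placement `"ahead"` or `"behind"`.
#' @param a Eccentricity slope for that placement (used by C and D).
#' @param speed Pursuit speed in deg/s (default 10).
#' @return Predicted PSE in degrees on the eccentricity axis.
#' @export
predict_pse <- function(model, fixation_pse, soa_ms, placement, a = NA_real_,
                        speed = 10) {
  model <- match.arg(model, c("A", "B", "C", "D"))
  if (model %in% c("C", "D") && any(!is.finite(a))) {
    stop("models C and D need a finite eccentricity slope a", call. = FALSE)
  }
  out <- fixation_pse
  if (model %in% c("B", "D")) {
    out <- out + retinal_shift(soa_ms, speed, placement)
  }
  if (model %in% c("C", "D")) {
    out <- out + compensation_shift(a, soa_ms, speed, placement)
  }
  out
}

#' Fit absolute mislocalization against retinal eccentricity
#'
#' Ordinary least squares of the mislocalization (perceived minus actual
#' position, eccentricity axis) on the retinal eccentricity of the flash,
#' separately per placement (and per subject when a `subject` column is
#' present), on trial-level data. The slope `a` is the eccentricity effect:
#' degrees of mislocalization per degree of retinal eccentricity.
#'
#' @param absolute_trials Tibble of QC-valid `pursuit_absolute` trials with
#'   columns `placement`, `hemifield`, `target_deg` (actual flash position,
#'   screen axis), `perceived_deg` (decoded ruler report, screen axis), and
#'   `eye_at_flash_deg` (eye position at the flash, screen axis); optionally
#'   `subject`.
#' @return Tibble with one row per (subject x) placement: `slope`,
#'   `intercept`, `n_points`, `r2`.
#' @export
fit_eccentricity <- function(absolute_trials) {
  need <- c("placement", "hemifield", "target_deg", "perceived_deg",
            "eye_at_flash_deg")
  missing_cols <- setdiff(need, names(absolute_trials))
  if (length(missing_cols) > 0) {
    stop("fit_eccentricity: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::mutate(absolute_trials,
    misloc_deg = to_eccentricity_axis(.data$perceived_deg, .data$hemifield) -
      to_eccentricity_axis(.data$target_deg, .data$hemifield),
    retinal_ecc_deg = retinal_position(.data$target_deg,
                                       .data$eye_at_flash_deg,
                                       .data$hemifield))
  keys <- intersect(c("subject", "placement"), names(df))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      if (length(unique(g$retinal_ecc_deg)) < 2) {
        stop("fit_eccentricity: a single eccentricity level leaves the ",
             "slope undefined", call. = FALSE)
      }
      fit <- stats::lm(misloc_deg ~ retinal_ecc_deg, data = g)
      r2 <- summary(fit)$r.squared
      tibble::tibble(slope = unname(stats::coef(fit)[2]),
                     intercept = unname(stats::coef(fit)[1]),
                     n_points = nrow(g), r2 = r2)
    }) |>
    dplyr::ungroup()
}

#' Evaluate model predictions against measured PSEs
#'
#' Regresses predicted on measured PSEs (ordinary least squares), computes the
#' Pearson correlation, and the mean and SD of the pointwise distances of the
#' (measured, predicted) points to the identity line. By default the distance
#' is geometric (perpendicular), `|p - m| / sqrt(2)`; `distance = "vertical"`
#' uses `|p - m|`.
#'
#' @param predicted,measured Numeric vectors of matched PSEs (>= 3 pairs).
#' @param model Optional model label carried into the result.
#' @param distance `"perpendicular"` (default) or `"vertical"`.
#' @return One-row tibble: `model`, `slope`, `intercept`, `pearson_r`,
#'   `d_mean`, `d_sd`, `n_points`.
#' @export
evaluate_model <- function(predicted, measured, model = NA_character_,
                           distance = c("perpendicular", "vertical")) {
  distance <- match.arg(distance)
  if (length(predicted) != length(measured)) {
    stop("predicted and measured must be the same length", call. = FALSE)
  }
  ok <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[ok]; measured <- measured[ok]
  if (length(predicted) < 3) {
    stop("evaluate_model needs at least 3 matched pairs", call. = FALSE)
  }
  if (stats::var(measured) == 0) {
    stop("evaluate_model: zero variance in measured PSEs, slope undefined",
         call. = FALSE)
  }
  fit <- stats::lm(predicted ~ measured)
  d <- abs(predicted - measured)
  if (distance == "perpendicular") d <- d / sqrt(2)
  tibble::tibble(model = model,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(predicted, measured),
                 d_mean = mean(d),
                 d_sd = stats::sd(d),
                 n_points = length(predicted))
}

#' Rank model evaluations
#'
#' Ascending by mean distance to the identity line, ties broken by
#' |slope - 1| ascending, remaining ties kept in input order. The full
#' ranking is returned, never only the winner.
#'
#' @param evaluations Tibble of [evaluate_model()] rows (>= 1).
#' @return The same tibble, ordered best first, with a `rank` column.
#' @export
select_model <- function(evaluations) {
  if (nrow(evaluations) < 1) {
    stop("select_model needs at least one evaluation", call. = FALSE)
  }
  ord <- order(evaluations$d_mean, abs(evaluations$slope - 1))
  out <- evaluations[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
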