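# Shared builders for deterministic, noise-controlled test objects.

# An observer with all stochastic nuisances switched off.
quiet_observer <- function(...) {
  make_observer(1, vary = FALSE,
                overrides = utils::modifyList(
                  list(saccade_rate_hz = 0, blink_prob = 0,
                       trace_noise_deg = 0, gain_sd = 0, pursuit_gain = 1,
                       lapse = 0, guess = 0),
                  list(...)))
}

pursuit_cond <- function(soa_ms = 200, direction = "rightward",
                         placement = "ahead", phase = "fine2") {
  condition("pursuit_relative", soa_ms, pursuit_direction = direction,
            placement = placement, phase = phase)
}

absolute_cond <- function(soa_ms = 0, direction = "rightward",
                          placement = "ahead") {
  condition("pursuit_absolute", soa_ms, pursuit_direction = direction,
            placement = placement)
}

fixation_cond <- function(soa_ms = 200, hemifield = "right") {
  condition("fixation_relative", soa_ms, hemifield = hemifield)
}

# Binomial draws from a known psychometric curve, binned.
binned_from_truth <- function(levels, n_per_level, pse, sigma,
                              guess = 0, lapse = 0, seed = 1) {
  withr::with_seed(seed, {
    p <- psychometric_prob(levels, pse, sigma, guess, lapse)
    tibble::tibble(level = levels,
                   k = stats::rbinom(length(levels), n_per_level, p),
                   n = n_per_level)
  })
}

# The eight per-subject compensation shifts of the published summary table.
published_shifts <- function() {
  tibble::tibble(
    subject = 1:8,
    ahead = c(0.99, 0.59, 0.48, 2.40, 0.74, 0.86, 0.40, 0.31),
    behind = c(-0.55, -0.81, -0.52, -0.43, -0.73, -0.75, -1.63, -0.54))
}
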