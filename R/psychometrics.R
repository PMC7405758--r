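#' Pool valid trials into binned responses
#'
#' Recodes the raw left/right key into a "target judged more eccentric"
#' response (the judgment and the key coincide in the right hemifield and are
#' mirrored in the left), maps target offsets onto the eccentricity axis, and
#' bins per condition cell. For the fixation task, left- and right-hemifield
#' trials are pooled before fitting, one bin set per SOA. For the pursuit
#' task, the two fine phases are pooled per (SOA x direction x placement)
#' cell; fits are done per direction and the parameters averaged across
#' leftward/rightward afterwards ([average_lr()]).
#'
#' @param trials Trial tibble; rows with `qc_valid == FALSE` are dropped
#'   (a missing `qc_valid` column means all trials are taken as valid).
#' @param task `"fixation_relative"` or `"pursuit_relative"`.
#' @param phases Pursuit phases to pool (default the two fine phases; the
#'   coarse pre-experiment can be binned on its own for interim centring).
#' @return Tibble of binned responses: grouping columns, `level`
#'   (eccentricity axis, deg), `k` (judged more eccentric), `n`.
#' @export
pool_trials <- function(trials, task = c("fixation_relative",
                                         "pursuit_relative"),
                        phases = c("fine1", "fine2")) {
  task <- match.arg(task)
  df <- trials[trials$task == task, , drop = FALSE]
  if ("qc_valid" %in% names(df)) df <- df[df$qc_valid, , drop = FALSE]
  if (task == "pursuit_relative") {
    df <- df[df$phase %in% phases, , drop = FALSE]
  }
  if (nrow(df) == 0) return(tibble::tibble())
  df$judged_ecc <- ifelse(df$hemifield == "right",
                          df$response_right, 1L - df$response_right)
  df$level <- to_eccentricity_axis(df$offset_deg, df$hemifield)
  keys <- if (task == "fixation_relative") "soa_ms" else
    c("soa_ms", "pursuit_direction", "placement")
  keys <- c(intersect("subject", names(df)), keys)
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "level")))) |>
    dplyr::summarise(k = sum(.data$judged_ecc), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "level"))))
}

neg_loglik_psy <- function(par, level, k, n) {
  p <- psychometric_prob(level, par[1], exp(par[2]), par[3], par[4])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

# analytic gradient of the negative binomial log-likelihood in
# (m, log sigma, guess, lapse)
neg_loglik_psy_grad <- function(par, level, k, n) {
  m <- par[1]; sigma <- exp(par[2]); g <- par[3]; l <- par[4]
  z <- (level - m) / sigma
  Phi <- stats::pnorm(z); phi <- stats::dnorm(z)
  p <- pmin(pmax(g + (1 - g - l) * Phi, 1e-12), 1 - 1e-12)
  w <- -(k / p - (n - k) / (1 - p))
  c(sum(w * (-(1 - g - l) * phi / sigma)),
    sum(w * (-(1 - g - l) * phi * z)),
    sum(w * (1 - Phi)),
    sum(w * (-Phi)))
}

#' Fit a cumulative-Gaussian psychometric function by maximum likelihood
#'
#' Maximises the binomial log-likelihood of
#' `psi(x) = guess + (1 - guess - lapse) * Phi((x - m) / sigma)` over the
#' binned responses; the PSE is `m`, the point where `psi` is halfway
#' between the asymptotes. The asymptote parameters are free within
#' \[0, `asymptote_max`\] (default 0.06). Five optimisation starts are seeded
#' from quantile heuristics; the convergence flag is honest, and degenerate
#' data (all 0s or all 1s) yield a non-converged fit with infinite CI.
#'
#' @param binned One cell of [pool_trials()] output: columns `level`, `k`,
#'   `n` with at least 4 distinct levels.
#' @param asymptote_max Upper bound for guess and lapse rates.
#' @return A `psychometric_fit` list: `pse`, `sigma`, `guess`, `lapse`,
#'   `loglik`, `pse_ci95` (NA until [bootstrap_pse_ci()]), `converged`,
#'   `n_levels`, `n_trials`, and the input data.
#' @export
fit_psychometric <- function(binned, asymptote_max = 0.06) {
  stopifnot(all(c("level", "k", "n") %in% names(binned)))
  binned <- binned[order(binned$level), , drop = FALSE]
  if (nrow(binned) < 4) {
    stop("fit_psychometric needs at least 4 distinct levels", call. = FALSE)
  }
  if (any(binned$k < 0 | binned$k > binned$n)) {
    stop("fit_psychometric: counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  lev <- binned$level; k <- binned$k; n <- binned$n
  span <- diff(range(lev))
  degenerate <- all(k == 0) || all(k == n)

  # quantile-based heuristics for the starts
  prop <- (k + 0.5) / (n + 1)
  m0 <- tryCatch(stats::approx(prop, lev, xout = 0.5, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(m0)) m0 <- stats::weighted.mean(lev, n)
  q25 <- tryCatch(stats::approx(prop, lev, xout = 0.25, ties = mean)$y,
                  error = function(e) NA_real_)
  q75 <- tryCatch(stats::approx(prop, lev, xout = 0.75, ties = mean)$y,
                  error = function(e) NA_real_)
  s0 <- if (is.finite(q25) && is.finite(q75) && q75 > q25) {
    (q75 - q25) / 1.349
  } else {
    span / 4
  }
  s0 <- min(max(s0, 0.05), 4 * span)

  lower <- c(min(lev) - 5, log(0.02), 0, 0)
  upper <- c(max(lev) + 5, log(4 * span + 1), asymptote_max, asymptote_max)
  starts <- list(
    c(m0, log(s0), 0.01, 0.01),
    c(m0, log(2 * s0), 0.001, 0.001),
    c(m0 + span / 8, log(s0 / 2), 0.03, 0.03),
    c(m0 - span / 8, log(s0), 0.02, 0.02),
    c(stats::weighted.mean(lev, n), log(span / 3), 0.01, 0.01))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    res <- tryCatch(
      stats::optim(st, neg_loglik_psy, gr = neg_loglik_psy_grad,
                   level = lev, k = k, n = n,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  converged <- !is.null(best) && best$convergence == 0 && !degenerate
  if (is.null(best)) {
    best <- list(par = c(m0, log(s0), 0.01, 0.01),
                 value = neg_loglik_psy(c(m0, log(s0), 0.01, 0.01),
                                        lev, k, n))
  }
  structure(
    list(pse = unname(best$par[1]), sigma = exp(unname(best$par[2])),
         guess = unname(best$par[3]), lapse = unname(best$par[4]),
         loglik = -best$value,
         pse_ci95 = if (converged) c(NA_real_, NA_real_) else c(-Inf, Inf),
         converged = converged,
         n_levels = nrow(binned), n_trials = sum(n),
         data = binned),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> PSE %+.3f deg, sigma %.3f deg, guess %.3f, lapse %.3f\n",
    x$pse, x$sigma, x$guess, x$lapse))
  if (all(is.finite(x$pse_ci95))) {
    cat(sprintf("  95%% CI [%.3f, %.3f]\n", x$pse_ci95[1], x$pse_ci95[2]))
  }
  cat(sprintf("  %d levels, %d trials, loglik %.2f, converged: %s\n",
              x$n_levels, x$n_trials, x$loglik, x$converged))
  invisible(x)
}

#' Bootstrap 95% confidence interval for the PSE
#'
#' Nonparametric bootstrap over the per-level binomial counts: each resample
#' redraws `k* ~ Binomial(n_l, k_l / n_l)` at every level, refits, and the
#' 2.5/97.5 percentiles of the resampled PSEs form the interval. If more
#' than 20% of the refits fail to converge the interval is widened by 50%
#' about the point estimate, with a warning.
#'
#' @param binned Binned responses the fit was computed from.
#' @param fit The [fit_psychometric()] result (must be converged).
#' @param n_boot Number of resamples (default 999).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return Numeric interval `c(lo, hi)` in degrees.
#' @export
bootstrap_pse_ci <- function(binned, fit, n_boot = 999, seed = 1) {
  if (!fit$converged) {
    stop("bootstrap_pse_ci needs a converged fit", call. = FALSE)
  }
  binned <- binned[order(binned$level), , drop = FALSE]
  prop <- binned$k / binned$n
  pses <- withr::with_seed(as.integer(seed %% 2147483647L), {
    vapply(seq_len(n_boot), function(b) {
      res <- binned
      res$k <- stats::rbinom(nrow(res), res$n, prop)
      f <- tryCatch(suppressWarnings(fit_psychometric(res)),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) NA_real_ else f$pse
    }, numeric(1))
  })
  frac_bad <- mean(is.na(pses))
  ci <- unname(stats::quantile(pses, c(0.025, 0.975), na.rm = TRUE))
  if (frac_bad > 0.2) {
    warning(sprintf(
      "bootstrap_pse_ci: %.0f%% of refits did not converge; widening the interval",
      100 * frac_bad), call. = FALSE)
    ci <- fit$pse + 1.5 * (ci - fit$pse)
  }
  ci
}

#' Average leftward and rightward pursuit fits
#'
#' Arithmetic mean of PSE, sigma, guess, and lapse across the two pursuit
#' directions of the same (SOA x placement) cell; confidence intervals are
#' combined conservatively as the union hull. If one side is missing the
#' other is passed through with a flag.
#'
#' @param fit_left,fit_right `psychometric_fit` objects (either may be NULL).
#' @return A `psychometric_fit` with an extra `one_sided` flag.
#' @export
average_lr <- function(fit_left, fit_right) {
  if (is.null(fit_left) && is.null(fit_right)) {
    stop("average_lr: both fits are missing", call. = FALSE)
  }
  if (is.null(fit_left) || is.null(fit_right)) {
    out <- if (is.null(fit_left)) fit_right else fit_left
    out$one_sided <- TRUE
    return(out)
  }
  structure(
    list(pse = mean(c(fit_left$pse, fit_right$pse)),
         sigma = mean(c(fit_left$sigma, fit_right$sigma)),
         guess = mean(c(fit_left$guess, fit_right$guess)),
         lapse = mean(c(fit_left$lapse, fit_right$lapse)),
         loglik = fit_left$loglik + fit_right$loglik,
         pse_ci95 = c(min(fit_left$pse_ci95[1], fit_right$pse_ci95[1]),
                      max(fit_left$pse_ci95[2], fit_right$pse_ci95[2])),
         converged = fit_left$converged && fit_right$converged,
         n_levels = max(fit_left$n_levels, fit_right$n_levels),
         n_trials = fit_left$n_trials + fit_right$n_trials,
         one_sided = FALSE),
    class = "psychometric_fit")
}
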