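#' Cohen's dz from a paired t statistic
#'
#' Within-subject effect size: `|t| / sqrt(n)` with `n` participants.
#'
#' @param t Paired t statistic.
#' @param n Number of participants.
#' @return Non-negative effect size.
#' @export
cohens_dz <- function(t, n) {
  stopifnot(n >= 1)
  abs(t) / sqrt(n)
}

#' Paired t test with effect size
#'
#' Standard paired-sample t test on the differences `x - y`, with Cohen's dz
#' attached. One-tailed tests take their direction from `alternative`.
#'
#' @param x,y Paired numeric samples of equal length >= 2, no missing pairs.
#' @param tails `"two"` (default) or `"one"`.
#' @param alternative Direction for one-tailed tests: `"greater"` (default)
#'   or `"less"` for the mean difference.
#' @param label Optional label carried into the result.
#' @return One-row tibble: `label`, `t`, `df`, `p`, `dz`, `tails`.
#' @export
paired_t <- function(x, y, tails = c("two", "one"),
                     alternative = c("greater", "less"),
                     label = NA_character_) {
  tails <- match.arg(tails)
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 2) {
    stop("paired_t needs equal-length samples of at least 2 pairs",
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("paired_t: missing pairs are not allowed", call. = FALSE)
  }
  d <- x - y
  if (stats::var(d) == 0 && !all(d == 0)) {
    stop("paired_t: zero-variance nonzero differences leave t undefined",
         call. = FALSE)
  }
  if (all(d == 0)) {
    return(tibble::tibble(label = label, t = 0, df = length(x) - 1L,
                          p = 1, dz = 0, tails = tails))
  }
  alt <- if (tails == "two") "two.sided" else alternative
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  tibble::tibble(label = label, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 dz = cohens_dz(unname(tt$statistic), length(x)),
                 tails = tails)
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down procedure: p values sorted ascending, the i-th smallest
#' compared to `alpha / (m - i + 1)`, stopping at the first failure;
#' decisions are mapped back to the input order. Less conservative than the
#' classical Bonferroni correction while controlling the family-wise error
#' rate.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @param alpha Family-wise error rate (default 0.05).
#' @return Tibble in input order: `p`, `p_holm` (adjusted), `significant`.
#' @export
holm_correction <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(tibble::tibble(p = numeric(), p_holm = numeric(),
                          significant = logical()))
  }
  if (any(p_values < 0 | p_values > 1)) {
    stop("holm_correction: p values must lie in [0, 1]", call. = FALSE)
  }
  p_holm <- stats::p.adjust(p_values, method = "holm")
  tibble::tibble(p = p_values, p_holm = p_holm,
                 significant = p_holm <= alpha)
}

#' Summarise per-subject compensation shifts
#'
#' Arithmetic mean and sample SD (n - 1 denominator) per placement column of
#' a per-subject shift table.
#'
#' @param per_subject_shifts Tibble or data frame whose numeric columns hold
#'   per-subject shifts (>= 2 subjects), e.g. columns `ahead` and `behind`.
#' @return Tibble with one row per column: `placement`, `mean`, `sd`, `n`.
#' @export
summarize_shift_table <- function(per_subject_shifts) {
  num <- per_subject_shifts[vapply(per_subject_shifts, is.numeric,
                                   logical(1))]
  if (nrow(num) < 2) {
    stop("summarize_shift_table needs at least 2 subjects", call. = FALSE)
  }
  tibble::tibble(
    placement = names(num),
    mean = unname(vapply(num, mean, numeric(1))),
    sd = unname(vapply(num, stats::sd, numeric(1))),
    n = nrow(num))
}
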