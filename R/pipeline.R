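#' Fit all per-subject PSEs of a dataset
#'
#' Fixation fits per subject and SOA (left/right hemifields pooled before
#' fitting); pursuit fits per subject, SOA, placement, and direction, with
#' the directional fits averaged ([average_lr()]) into one row per
#' (subject x SOA x placement). Bootstrap CIs are attached when
#' `n_boot > 0`.
#'
#' @param trials Trial tibble with QC columns.
#' @param n_boot Bootstrap resamples per fit (0 disables CIs).
#' @param seed Integer seed for the bootstrap.
#' @return Tibble: `subject`, `task`, `soa_ms`, `placement`, `pse`, `sigma`,
#'   `guess`, `lapse`, `ci_lo`, `ci_hi`, `n_trials`, `converged`.
#' @export
fit_pse_table <- function(trials, n_boot = 0, seed = 1) {
  rows <- list()
  fix <- pool_trials(trials, "fixation_relative")
  if (nrow(fix) > 0) {
    fix_cells <- dplyr::distinct(fix, .data$subject, .data$soa_ms)
    for (i in seq_len(nrow(fix_cells))) {
      cell <- fix[fix$subject == fix_cells$subject[i] &
                    fix$soa_ms == fix_cells$soa_ms[i], , drop = FALSE]
      f <- suppressWarnings(fit_psychometric(cell))
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0 && f$converged) {
        ci <- bootstrap_pse_ci(cell, f, n_boot = n_boot,
                               seed = derive_seed(seed, i, 23))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = fix_cells$subject[i], task = "fixation_relative",
        soa_ms = fix_cells$soa_ms[i], placement = "na",
        pse = f$pse, sigma = f$sigma, guess = f$guess, lapse = f$lapse,
        ci_lo = ci[1], ci_hi = ci[2], n_trials = f$n_trials,
        converged = f$converged)
    }
  }
  pur <- pool_trials(trials, "pursuit_relative")
  if (nrow(pur) > 0) {
    pur_cells <- dplyr::distinct(pur, .data$subject, .data$soa_ms,
                                 .data$placement)
    for (i in seq_len(nrow(pur_cells))) {
      fits <- purrr::map(c("leftward", "rightward"), function(dir) {
        cell <- pur[pur$subject == pur_cells$subject[i] &
                      pur$soa_ms == pur_cells$soa_ms[i] &
                      pur$placement == pur_cells$placement[i] &
                      pur$pursuit_direction == dir, , drop = FALSE]
        tryCatch(suppressWarnings(fit_psychometric(cell)),
                 error = function(e) NULL)
      })
      if (all(purrr::map_lgl(fits, is.null))) next
      f <- average_lr(fits[[1]], fits[[2]])
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0) {
        cis <- purrr::imap(fits, function(ft, j) {
          if (is.null(ft) || !ft$converged) return(NULL)
          dir <- c("leftward", "rightward")[j]
          cell <- pur[pur$subject == pur_cells$subject[i] &
                        pur$soa_ms == pur_cells$soa_ms[i] &
                        pur$placement == pur_cells$placement[i] &
                        pur$pursuit_direction == dir, , drop = FALSE]
          bootstrap_pse_ci(cell, ft, n_boot = n_boot,
                           seed = derive_seed(seed, 1000 + i, j))
        })
        cis <- purrr::compact(cis)
        if (length(cis) > 0) {
          ci <- c(min(purrr::map_dbl(cis, 1)), max(purrr::map_dbl(cis, 2)))
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = pur_cells$subject[i], task = "pursuit_relative",
        soa_ms = pur_cells$soa_ms[i], placement = pur_cells$placement[i],
        pse = f$pse, sigma = f$sigma, guess = f$guess, lapse = f$lapse,
        ci_lo = ci[1], ci_hi = ci[2], n_trials = f$n_trials,
        converged = f$converged)
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-subject model predictions and evaluations
#'
#' For every subject, non-simultaneous SOA, and placement, predicts the
#' pursuit PSE under models A-D from the subject's fixation PSE and
#' eccentricity slope, pairs it with the measured pursuit PSE, and
#' evaluates each model against the identity line.
#'
#' @param pse_table Output of [fit_pse_table()].
#' @param ecc_table Output of [fit_eccentricity()] (per subject and
#'   placement).
#' @param speed Pursuit speed, deg/s.
#' @param distance Distance definition for [evaluate_model()].
#' @return List: `predictions` (per subject x cell x model) and
#'   `evaluations` (per model, ranked by [select_model()]).
#' @export
compare_models <- function(pse_table, ecc_table, speed = 10,
                           distance = c("perpendicular", "vertical")) {
  distance <- match.arg(distance)
  meas <- pse_table[pse_table$task == "pursuit_relative" &
                      pse_table$soa_ms != 0, , drop = FALSE]
  fixs <- pse_table[pse_table$task == "fixation_relative", , drop = FALSE]
  preds <- list()
  for (i in seq_len(nrow(meas))) {
    fx <- fixs$pse[fixs$subject == meas$subject[i] &
                     fixs$soa_ms == meas$soa_ms[i]]
    a <- ecc_table$slope[ecc_table$subject == meas$subject[i] &
                           ecc_table$placement == meas$placement[i]]
    if (length(fx) != 1 || length(a) != 1) next
    for (model in c("A", "B", "C", "D")) {
      preds[[length(preds) + 1L]] <- tibble::tibble(
        subject = meas$subject[i], soa_ms = meas$soa_ms[i],
        placement = meas$placement[i], model = model,
        predicted_pse = predict_pse(model, fx, meas$soa_ms[i],
                                    meas$placement[i], a = a, speed = speed),
        measured_pse = meas$pse[i])
    }
  }
  predictions <- dplyr::bind_rows(preds)
  if (nrow(predictions) == 0) {
    stop("compare_models: no matched (subject x condition) cells",
         call. = FALSE)
  }
  evals <- predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(function(g, key) {
      evaluate_model(g$predicted_pse, g$measured_pse,
                     distance = distance)[, -1]
    }) |>
    dplyr::ungroup()
  list(predictions = predictions, evaluations = select_model(evals))
}

default_battery <- function() {
  tibble::tribble(
    ~label, ~soa_ms, ~placement_a, ~placement_b, ~tails, ~alternative,
    "neg SOA: ahead vs fixation",  -200, "ahead",  "fixation", "two", "greater",
    "neg SOA: behind vs fixation", -200, "behind", "fixation", "two", "greater",
    "neg SOA: ahead vs behind",    -200, "ahead",  "behind",   "two", "greater",
    "fixation: pos vs neg SOA",     NA,  "fix_pos", "fix_neg", "one", "greater",
    "pos SOA: ahead vs fixation",   200, "ahead",  "fixation", "two", "greater",
    "pos SOA: behind vs fixation",  200, "behind", "fixation", "two", "greater",
    "pos SOA: ahead vs behind",     200, "ahead",  "behind",   "two", "greater",
    "ahead: pos vs neg SOA",        NA,  "ahead_pos", "ahead_neg", "two", "greater",
    "behind: pos vs neg SOA",       NA,  "behind_pos", "behind_neg", "two", "greater")
}

battery_vector <- function(pse_table, spec, soa_ms) {
  pick <- function(task, soa, placement) {
    df <- pse_table[pse_table$task == task & pse_table$soa_ms == soa, ,
                    drop = FALSE]
    if (task == "pursuit_relative") {
      df <- df[df$placement == placement, , drop = FALSE]
    }
    df <- df[order(df$subject), , drop = FALSE]
    stats::setNames(df$pse, df$subject)
  }
  switch(spec,
    fixation = pick("fixation_relative", soa_ms, NA),
    ahead = pick("pursuit_relative", soa_ms, "ahead"),
    behind = pick("pursuit_relative", soa_ms, "behind"),
    fix_pos = pick("fixation_relative", 200, NA),
    fix_neg = pick("fixation_relative", -200, NA),
    ahead_pos = pick("pursuit_relative", 200, "ahead"),
    ahead_neg = pick("pursuit_relative", -200, "ahead"),
    behind_pos = pick("pursuit_relative", 200, "behind"),
    behind_neg = pick("pursuit_relative", -200, "behind"),
    stop("unknown battery cell '", spec, "'", call. = FALSE))
}

#' Run the paired-comparison battery on a PSE table
#'
#' Each battery row compares two per-subject PSE vectors with a paired t
#' test; Holm's sequential Bonferroni correction is applied across the
#' battery.
#'
#' @param pse_table Output of [fit_pse_table()].
#' @param battery Declarative comparison table (see `default_battery`, the
#'   study's own comparisons).
#' @param alpha Family-wise error rate.
#' @return Tibble of test results with `p_holm` and `holm_significant`.
#' @export
run_battery <- function(pse_table, battery = default_battery(),
                        alpha = 0.05) {
  res <- purrr::pmap_dfr(battery, function(label, soa_ms, placement_a,
                                           placement_b, tails, alternative) {
    x <- battery_vector(pse_table, placement_a, soa_ms)
    y <- battery_vector(pse_table, placement_b, soa_ms)
    common <- intersect(names(x), names(y))
    if (length(common) < 2) {
      return(tibble::tibble(label = label, t = NA_real_, df = NA_integer_,
                            p = NA_real_, dz = NA_real_, tails = tails))
    }
    paired_t(x[common], y[common], tails = tails,
             alternative = alternative, label = label)
  })
  ok <- !is.na(res$p)
  res$p_holm <- NA_real_
  res$holm_significant <- NA
  if (any(ok)) {
    hc <- holm_correction(res$p[ok], alpha = alpha)
    res$p_holm[ok] <- hc$p_holm
    res$holm_significant[ok] <- hc$significant
  }
  res
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a dataset, applies QC, fits all PSEs, fits the
#' eccentricity regressions, derives the per-subject compensation-shift
#' table and its mean +/- SD summary, compares models A-D against the
#' measured pursuit PSEs, and runs the statistical battery. With
#' `config$out_dir` set, all tables are written as tab-separated text plus a
#' JSON run manifest; a fixed seed yields byte-identical outputs. Any stage
#' failure aborts with a stage-labelled error and removes partial outputs.
#'
#' @param config Named list: `seed`; either `trials` (+ optional `traces`)
#'   for pre-made data or the generator settings `n_subjects`,
#'   `observer_spec`, `counts`, `simulate_traces`; `n_boot` (default 0);
#'   `distance`; `speed`; `battery`; `shift_table_override` (a per-subject
#'   shift table used in place of the fitted one, e.g. published values);
#'   `out_dir`.
#' @return List: `trials`, `qc`, `pse_table`, `ecc_table`, `shift_table`,
#'   `shift_summary`, `predictions`, `model_evaluations`, `tests`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(
    list(seed = 1, n_subjects = 8, observer_spec = list(), counts = list(),
         simulate_traces = TRUE, n_boot = 0, distance = "perpendicular",
         speed = 10, battery = default_battery(),
         shift_table_override = NULL, trials = NULL, traces = NULL,
         out_dir = NULL),
    config)
  written <- character()
  ok <- FALSE
  on.exit({
    if (!ok && length(written) > 0) unlink(written)
  })
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dataset <- stage("generate", {
    if (!is.null(cfg$trials)) {
      list(trials = cfg$trials, traces = cfg$traces %||% list(),
           observers = NULL,
           manifest = list(source = "user-supplied", seed = cfg$seed))
    } else {
      generate_dataset(n_subjects = cfg$n_subjects,
                       observer_spec = cfg$observer_spec,
                       counts = cfg$counts, seed = cfg$seed,
                       simulate_traces = cfg$simulate_traces,
                       speed = cfg$speed)
    }
  })
  trials <- dataset$trials
  if (!"qc_valid" %in% names(trials)) {
    trials <- stage("qc", exclude_trials(trials, dataset$traces,
                                         speed = cfg$speed))
  }
  qc <- stage("qc", qc_report(trials))

  pse_table <- stage("fit", fit_pse_table(trials, n_boot = cfg$n_boot,
                                          seed = cfg$seed))

  ecc_table <- stage("models", {
    abs_trials <- trials[trials$task == "pursuit_absolute" &
                           trials$qc_valid, , drop = FALSE]
    fit_eccentricity(decode_absolute_trials(abs_trials))
  })

  shift_table <- stage("models", {
    if (!is.null(cfg$shift_table_override)) {
      cfg$shift_table_override
    } else {
      ecc_table |>
        dplyr::mutate(shift = compensation_shift(.data$slope, 200,
                                                 cfg$speed,
                                                 .data$placement)) |>
        dplyr::select(dplyr::all_of(c("subject", "placement", "shift"))) |>
        tidyr::pivot_wider(names_from = "placement",
                           values_from = "shift")
    }
  })
  shift_summary <- stage("models", summarize_shift_table(
    shift_table[, setdiff(names(shift_table), "subject"), drop = FALSE]))

  comparison <- stage("models", compare_models(pse_table, ecc_table,
                                               speed = cfg$speed,
                                               distance = cfg$distance))

  tests <- stage("stats", run_battery(pse_table, battery = cfg$battery))

  manifest <- list(seed = cfg$seed, config_hash = cfg_hash(cfg),
                   generator = dataset$manifest,
                   r_version = as.character(getRversion()))

  if (!is.null(cfg$out_dir)) {
    stage("report", {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      wt <- function(df, file) {
        p <- file.path(cfg$out_dir, file)
        readr::write_tsv(df, p)
        written <<- c(written, p)
      }
      wt(trials, "trials.tsv")
      wt(qc, "qc_report.tsv")
      wt(pse_table, "pse_table.tsv")
      wt(ecc_table, "eccentricity_table.tsv")
      summary_rows <- shift_summary |>
        dplyr::select(dplyr::all_of(c("placement", "mean", "sd")))
      wt(summary_rows, "shift_summary.tsv")
      wt(shift_table, "shift_table.tsv")
      wt(comparison$evaluations, "model_comparison.tsv")
      wt(comparison$predictions, "model_predictions.tsv")
      wt(tests, "tests.tsv")
      p <- file.path(cfg$out_dir, "manifest.json")
      write_manifest(manifest, p)
      written <<- c(written, p)
    })
  }
  ok <- TRUE
  list(trials = trials, qc = qc, pse_table = pse_table,
       ecc_table = ecc_table, shift_table = shift_table,
       shift_summary = shift_summary,
       predictions = comparison$predictions,
       model_evaluations = comparison$evaluations, tests = tests,
       manifest = manifest)
}

# Small stable hash of the configuration for the run manifest.
cfg_hash <- function(cfg) {
  cfg$trials <- NULL; cfg$traces <- NULL; cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
             collapse = "\n")
  bytes <- as.integer(charToRaw(s))
  x <- 0
  for (b in bytes) x <- (x * 31 + b) %% 2147483647
  x
}
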