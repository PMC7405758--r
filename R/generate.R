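#' Generate a complete synthetic experiment
#'
#' Simulates, per subject: a fixation-relative block, the full
#' coarse-to-fine pursuit-relative sweep (the fine grids are re-centred per
#' (placement x SOA) cell from interim PSE fits: fine1 on the coarse PSE
#' rounded to 1 deg, fine2 on the fine1 PSE rounded to 0.5 deg), and an
#' absolute ruler block. With `simulate_traces = TRUE` every trial gets a
#' 500-Hz eye trace, the trial-exclusion rules are applied, and trials are
#' topped up until the requested *valid* counts per condition cell are met;
#' with `simulate_traces = FALSE` all trials are clean and a single pass is
#' generated (useful for fast parameter-recovery studies).
#'
#' @param n_subjects Number of synthetic observers (default 8).
#' @param observer_spec Named list of observer overrides applied to every
#'   subject (e.g. `list(frame_model = "B")`); see [make_observer()].
#' @param counts List of per-cell counts: `fixation` (valid trials per
#'   hemifield x SOA cell; default 75, so L/R pooling gives 150 per SOA),
#'   `coarse` (trials per level in the coarse pre-experiment; default 5),
#'   `relative` (valid trials per pursuit cell per fine phase; default 75,
#'   so fine1 + fine2 give the 150 valid trials per condition), `absolute`
#'   (valid trials per pursuit condition; default 50).
#' @param seed Master integer seed; all per-trial streams derive from it.
#' @param simulate_traces Simulate eye traces and apply QC (default TRUE).
#' @param frame_drop_prob Per-trial probability of a logged frame drop.
#' @param speed Pursuit target speed, deg/s.
#' @return List: `trials` (tibble with QC columns), `traces` (named list of
#'   [eye_trace()], empty when traces are off), `observers` (list of
#'   ground-truth `observer_params` per subject), `manifest` (seeds and
#'   settings).
#' @export
generate_dataset <- function(n_subjects = 8, observer_spec = list(),
                             counts = list(), seed = 1,
                             simulate_traces = TRUE,
                             frame_drop_prob = 0.005, speed = 10) {
  cnt <- utils::modifyList(
    list(fixation = 75, coarse = 5, relative = 75, absolute = 50), counts)
  stopifnot(all(unlist(cnt) >= 1))

  env <- new.env()
  env$trials <- list()
  env$traces <- list()
  env$counter <- 0L
  observers <- vector("list", n_subjects)

  for (subj in seq_len(n_subjects)) {
    obs <- make_observer(derive_seed(seed, subj, 1),
                         overrides = observer_spec)
    observers[[subj]] <- obs

    # fixation block
    sim_block(env, subj, obs, "fixation_relative", "na", 0,
              min_valid = cnt$fixation, seed = seed,
              simulate_traces = simulate_traces,
              frame_drop_prob = frame_drop_prob, speed = speed)

    # coarse pursuit sweep (pre-experiment, single pass)
    coarse <- sim_block(env, subj, obs, "pursuit_relative", "coarse", 0,
                        min_valid = NULL, n_per_cell = cnt$coarse,
                        seed = seed, simulate_traces = simulate_traces,
                        frame_drop_prob = frame_drop_prob, speed = speed)
    ctr1 <- interim_centers(coarse, "coarse", round_to = 1)

    fine1 <- sim_block(env, subj, obs, "pursuit_relative", "fine1", ctr1,
                       min_valid = cnt$relative, seed = seed,
                       simulate_traces = simulate_traces,
                       frame_drop_prob = frame_drop_prob, speed = speed)
    ctr2 <- interim_centers(fine1, "fine1", round_to = 0.5, fallback = ctr1)

    sim_block(env, subj, obs, "pursuit_relative", "fine2", ctr2,
              min_valid = cnt$relative, seed = seed,
              simulate_traces = simulate_traces,
              frame_drop_prob = frame_drop_prob, speed = speed)

    sim_block(env, subj, obs, "pursuit_absolute", "na", 0,
              min_valid = cnt$absolute, seed = seed,
              simulate_traces = simulate_traces,
              frame_drop_prob = frame_drop_prob, speed = speed)
  }

  trials <- dplyr::bind_rows(env$trials)
  list(trials = trials, traces = env$traces, observers = observers,
       manifest = list(seed = seed, n_subjects = n_subjects,
                       counts = cnt, observer_spec = observer_spec,
                       simulate_traces = simulate_traces,
                       frame_drop_prob = frame_drop_prob, speed = speed))
}

# Simulate one block with optional valid-count top-up; appends trials and
# traces to env and returns this block's trials.
sim_block <- function(env, subj, obs, task, phase, center, min_valid,
                      n_per_cell = NULL, seed, simulate_traces,
                      frame_drop_prob, speed, max_iter = 8) {
  grid_len <- length(phase_grid(task, phase))
  block <- list()
  valid_tally <- NULL
  for (iter in seq_len(max_iter)) {
    if (is.null(min_valid)) {
      n_cell <- n_per_cell
    } else {
      deficit <- if (is.null(valid_tally)) min_valid else
        max(min_valid - min(valid_tally), 0)
      if (deficit == 0) break
      n_cell <- max(1, ceiling(deficit / grid_len * 1.2))
    }
    if (task == "pursuit_absolute") n_cell <- 2 * ceiling(n_cell / 2)
    sched <- build_schedule(task, phase, center, n_per_cell = n_cell,
                            seed = derive_seed(seed, subj, block_code(task,
                                                                      phase),
                                               iter))
    batch <- sim_batch(env, subj, obs, sched, seed, iter, simulate_traces,
                       frame_drop_prob, speed)
    block[[iter]] <- batch
    if (is.null(min_valid)) break
    all_so_far <- dplyr::bind_rows(block)
    valid_tally <- all_so_far |>
      dplyr::filter(.data$qc_valid) |>
      dplyr::count(.data$hemifield, .data$pursuit_direction,
                   .data$placement, .data$soa_ms) |>
      dplyr::pull(.data$n)
    n_cells_expected <- if (task == "fixation_relative") 6 else 12
    if (length(valid_tally) < n_cells_expected) {
      valid_tally <- c(valid_tally,
                       rep(0, n_cells_expected - length(valid_tally)))
    }
    if (min(valid_tally) >= min_valid) break
  }
  out <- dplyr::bind_rows(block)
  env$trials[[length(env$trials) + 1L]] <- out
  out
}

block_code <- function(task, phase) {
  match(paste(task, phase),
        c("fixation_relative na", "pursuit_relative coarse",
          "pursuit_relative fine1", "pursuit_relative fine2",
          "pursuit_absolute na"))
}

# Simulate responses (and traces/QC) for one scheduled batch.
sim_batch <- function(env, subj, obs, sched, seed, iter, simulate_traces,
                      frame_drop_prob, speed) {
  task <- sched$task[1]
  bc <- block_code(task, sched$phase[1])
  n <- nrow(sched)
  ids <- sprintf("s%03d_t%07d", subj, env$counter + seq_len(n))
  env$counter <- env$counter + n

  if (simulate_traces) {
    traces <- vector("list", n)
    for (i in seq_len(n)) {
      traces[[i]] <- simulate_eye_trace(sched[i, ], obs,
                                        seed = derive_seed(seed, subj, bc,
                                                           iter, i, 11),
                                        speed = speed)
    }
    names(traces) <- ids
  }

  if (task %in% c("fixation_relative", "pursuit_relative")) {
    batch <- simulate_relative_block(obs, sched,
                                     seed = derive_seed(seed, subj, bc,
                                                        iter, 13))
  } else {
    eye <- rep(NA_real_, n)
    if (simulate_traces) {
      for (i in seq_len(n)) {
        tr <- traces[[i]]
        ft <- flash_times(task, sched$soa_ms[i])
        idx <- which.min(abs(tr$t_ms - ft$target_ms))
        eye[i] <- tr$x_deg[idx]
      }
    }
    batch <- simulate_absolute_block(obs, sched,
                                     seed = derive_seed(seed, subj, bc,
                                                        iter, 17),
                                     eye_at_flash_deg = eye, speed = speed)
  }
  batch$subject <- subj
  batch$trace_id <- ids
  batch$frame_drop <- withr::with_seed(
    derive_seed(seed, subj, bc, iter, 19),
    stats::runif(n) < frame_drop_prob)

  if (simulate_traces) {
    batch <- exclude_trials(batch, traces, speed = speed)
    env$traces[ids] <- traces
  } else {
    batch$deviation_exceeded <- FALSE
    batch$saccade_blink_near_flash <- FALSE
    batch$missing_trace <- FALSE
    batch$qc_valid <- !batch$frame_drop
  }
  batch
}

# Interim PSE per (placement x SOA) cell, averaged over the two pursuit
# directions and rounded to the grid step of the next phase; falls back to
# the previous centres (or 0) when a cell cannot be fitted.
interim_centers <- function(block, phase, round_to, fallback = NULL) {
  cells <- tidyr::expand_grid(placement = c("ahead", "behind"),
                              soa_ms = c(-200, 0, 200))
  binned <- tryCatch(pool_trials(block, "pursuit_relative", phases = phase),
                     error = function(e) tibble::tibble())
  cells$center_deg <- vapply(seq_len(nrow(cells)), function(i) {
    placement <- cells$placement[i]; soa_ms <- cells$soa_ms[i]
    fb <- 0
    if (is.data.frame(fallback)) {
      hit <- fallback$placement == placement & fallback$soa_ms == soa_ms
      if (any(hit)) fb <- fallback$center_deg[which(hit)[1]]
    }
    if (nrow(binned) == 0) return(fb)
    # a quick empirical-probit regression is enough for grid centring
    pses <- vapply(c("leftward", "rightward"), function(dir) {
      cell <- binned[binned$placement == placement &
                       binned$soa_ms == soa_ms &
                       binned$pursuit_direction == dir, , drop = FALSE]
      if (nrow(cell) < 3 || sum(cell$n) == 0) return(NA_real_)
      z <- stats::qnorm((cell$k + 0.5) / (cell$n + 1))
      co <- tryCatch(stats::coef(stats::lm.wfit(
        cbind(1, cell$level), z, w = cell$n)),
        error = function(e) c(NA_real_, NA_real_))
      if (!all(is.finite(co)) || co[2] <= 0) return(NA_real_)
      unname(-co[1] / co[2])
    }, numeric(1))
    if (all(is.na(pses))) return(fb)
    round(mean(pses, na.rm = TRUE) / round_to) * round_to
  }, numeric(1))
  cells
}
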