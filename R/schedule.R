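#' Target-offset grid of a task phase
#'
#' The relative-task grids of the design: the fixation task presents the
#' target at +/-0.3, +/-1.0, +/-1.7, +/-2.5 deg around the reference; the
#' pursuit-relative task is run in three iterations with grids 0, +/-2, ...,
#' +/-8 deg (coarse), 0, +/-1, ..., +/-4 deg (fine1) and 0, +/-0.5, ..., +/-2
#' deg (fine2), the two fine grids being re-centred per subject and
#' condition. The absolute task flashes a single target at the reference
#' eccentricity (offset grid is \{0\}).
#'
#' @param task Task name (see [condition()]).
#' @param phase Phase name; only used for `"pursuit_relative"`.
#' @return Numeric vector of offsets in degrees.
#' @export
phase_grid <- function(task, phase = "na") {
  switch(task,
    fixation_relative = c(-2.5, -1.7, -1.0, -0.3, 0.3, 1.0, 1.7, 2.5),
    pursuit_relative = switch(phase,
      coarse = seq(-8, 8, by = 2),
      fine1 = seq(-4, 4, by = 1),
      fine2 = seq(-2, 2, by = 0.5),
      stop("phase grid undefined for pursuit_relative phase '", phase, "'",
           call. = FALSE)),
    pursuit_absolute = 0,
    stop("unknown task '", task, "'", call. = FALSE))
}

condition_cells <- function(task, phase = "na") {
  soas <- c(-200, 0, 200)
  if (task == "fixation_relative") {
    tidyr::expand_grid(task = task, phase = "na",
                       hemifield = c("left", "right"),
                       pursuit_direction = "none", placement = "na",
                       soa_ms = soas)
  } else {
    cells <- tidyr::expand_grid(task = task, phase = phase,
                                pursuit_direction = c("leftward", "rightward"),
                                placement = c("ahead", "behind"),
                                soa_ms = soas)
    cells$hemifield <- pursuit_hemifield(cells$pursuit_direction,
                                         cells$placement)
    cells[, c("task", "phase", "hemifield", "pursuit_direction",
              "placement", "soa_ms")]
  }
}

#' Build a pseudo-randomised trial schedule
#'
#' Crosses all condition cells of a task (2 hemifields x 3 SOAs for fixation;
#' 2 directions x 2 placements x 3 SOAs for the pursuit tasks) with the
#' phase's offset grid, repeats each offset `n_per_cell` times, and shuffles
#' the order under `seed`. For the fine pursuit phases the grid is translated
#' by a per-cell centre (given on the eccentricity axis, so the same centre
#' serves the leftward and rightward mirror cells); centres are forced to 0
#' for the fixation task, the coarse phase, and the absolute task. For the
#' absolute task, exactly half of each cell's trials carry a 0.4-deg ruler
#' shift; an odd `n_per_cell` is rounded down by one trial per cell, with a
#' warning, to keep the halves balanced.
#'
#' @param task Task name.
#' @param phase Phase for `"pursuit_relative"` (`"coarse"`, `"fine1"`,
#'   `"fine2"`); ignored otherwise.
#' @param center_deg Either a single centre (eccentricity axis, degrees) or a
#'   tibble with columns `placement`, `soa_ms`, `center_deg` giving one
#'   centre per (placement x SOA) cell.
#' @param n_per_cell Trials per offset level per condition cell (>= 1).
#' @param seed Integer seed for the trial order (and ruler-shift balance).
#' @return Tibble: condition columns, `offset_deg` (screen axis, relative to
#'   the reference), `ruler_shifted`.
#' @export
build_schedule <- function(task, phase = "na", center_deg = 0, n_per_cell = 1,
                           seed = 1) {
  stopifnot(n_per_cell >= 1)
  task <- match.arg(task,
    c("fixation_relative", "pursuit_relative", "pursuit_absolute"))
  if (task != "pursuit_relative") phase <- "na"
  if (task == "pursuit_relative" && phase == "na") {
    stop("pursuit_relative schedules need a phase", call. = FALSE)
  }
  cells <- condition_cells(task, phase)
  grid <- phase_grid(task, phase)
  centered <- task == "pursuit_relative" && phase %in% c("fine1", "fine2")
  if (!centered) center_deg <- 0

  n_cell <- n_per_cell
  if (task == "pursuit_absolute" && n_per_cell %% 2 == 1) {
    warning("odd n_per_cell for the absolute task: rounding down by one ",
            "trial per cell to balance the ruler-shift halves", call. = FALSE)
    n_cell <- n_per_cell - 1
    if (n_cell == 0) stop("n_per_cell too small after balancing",
                          call. = FALSE)
  }

  ctr_ecc <- if (is.data.frame(center_deg)) {
    hit <- match(paste(cells$placement, cells$soa_ms),
                 paste(center_deg$placement, center_deg$soa_ms))
    if (anyNA(hit)) {
      stop("center_deg table must give exactly one centre per ",
           "(placement x SOA) cell", call. = FALSE)
    }
    center_deg$center_deg[hit]
  } else {
    rep(center_deg, nrow(cells))
  }
  # centre is on the eccentricity axis; offsets are stored on screen axis
  ctr_screen <- to_eccentricity_axis(ctr_ecc, cells$hemifield)
  per_cell <- length(grid) * n_cell
  idx <- rep(seq_len(nrow(cells)), each = per_cell)
  offs <- as.vector(outer(rep(grid, each = n_cell), ctr_screen, `+`))
  shifted <- if (task == "pursuit_absolute") {
    rep(rep(c(TRUE, FALSE), length.out = per_cell), nrow(cells))
  } else {
    rep(FALSE, length(offs))
  }
  rows <- tibble::tibble(task = cells$task[idx], phase = cells$phase[idx],
                         hemifield = cells$hemifield[idx],
                         pursuit_direction = cells$pursuit_direction[idx],
                         placement = cells$placement[idx],
                         soa_ms = cells$soa_ms[idx],
                         offset_deg = offs, ruler_shifted = shifted)
  withr::with_seed(as.integer(seed %% 2147483647L),
                   rows[sample.int(nrow(rows)), , drop = FALSE])
}
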