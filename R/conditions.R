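#' Experimental condition descriptor
#'
#' A validated one-row tibble describing one cell of the design. The three
#' tasks are a two-flash relative judgment during fixation
#' (`"fixation_relative"`), the same judgment during smooth pursuit
#' (`"pursuit_relative"`, run in coarse / fine1 / fine2 phases), and a
#' single-flash ruler report during pursuit (`"pursuit_absolute"`).
#'
#' Fixation trials have `pursuit_direction = "none"` and `placement = "na"`;
#' pursuit trials must state whether the flashes are placed ahead of or
#' behind the pursuit target. For pursuit trials the stimulus hemifield is
#' implied: flashes ahead of a rightward-moving target lie in the right
#' hemifield, flashes behind it in the left hemifield, and vice versa; a
#' supplied `hemifield` that contradicts this is an error.
#'
#' @param task One of `"fixation_relative"`, `"pursuit_relative"`,
#'   `"pursuit_absolute"`.
#' @param soa_ms Stimulus onset asynchrony in ms, one of -200, 0, +200
#'   (positive: target after reference).
#' @param hemifield Stimulus hemifield, `"left"` or `"right"`. Required for
#'   fixation; derived from direction and placement for pursuit.
#' @param pursuit_direction `"leftward"`, `"rightward"`, or `"none"`.
#' @param placement `"ahead"`, `"behind"`, or `"na"`.
#' @param phase `"coarse"`, `"fine1"`, `"fine2"`, or `"na"`.
#' @return One-row tibble with the condition fields.
#' @export
condition <- function(task, soa_ms, hemifield = NULL,
                      pursuit_direction = "none", placement = "na",
                      phase = "na") {
  task <- match.arg(task,
    c("fixation_relative", "pursuit_relative", "pursuit_absolute"))
  phase <- match.arg(phase, c("coarse", "fine1", "fine2", "na"))
  pursuit_direction <- match.arg(pursuit_direction,
    c("leftward", "rightward", "none"))
  placement <- match.arg(placement, c("ahead", "behind", "na"))
  if (!soa_ms %in% c(-200, 0, 200)) {
    stop("soa_ms must be -200, 0 or 200", call. = FALSE)
  }
  if (task == "fixation_relative") {
    if (pursuit_direction != "none" || placement != "na") {
      stop("fixation trials have no pursuit direction or placement",
           call. = FALSE)
    }
    if (is.null(hemifield)) {
      stop("fixation trials need an explicit hemifield", call. = FALSE)
    }
    hemifield <- match_hemifield(hemifield)
    phase <- "na"
  } else {
    if (pursuit_direction == "none" || placement == "na") {
      stop("pursuit trials need a pursuit direction and a placement",
           call. = FALSE)
    }
    implied <- pursuit_hemifield(pursuit_direction, placement)
    if (!is.null(hemifield) && match_hemifield(hemifield) != implied) {
      stop("hemifield contradicts pursuit direction and placement",
           call. = FALSE)
    }
    hemifield <- implied
    if (task == "pursuit_absolute") phase <- "na"
  }
  tibble::tibble(task = task, phase = phase, hemifield = hemifield,
                 pursuit_direction = pursuit_direction,
                 placement = placement, soa_ms = soa_ms)
}

#' Hemifield implied by pursuit direction and flash placement
#'
#' @param pursuit_direction `"leftward"` or `"rightward"`.
#' @param placement `"ahead"` or `"behind"`.
#' @return `"left"` or `"right"` (vectorised).
#' @export
pursuit_hemifield <- function(pursuit_direction, placement) {
  ok_dir <- pursuit_direction %in% c("leftward", "rightward")
  ok_pl <- placement %in% c("ahead", "behind")
  if (!all(ok_dir) || !all(ok_pl)) {
    stop("pursuit_hemifield needs a moving direction and a flash placement",
         call. = FALSE)
  }
  rightward <- pursuit_direction == "rightward"
  ahead <- placement == "ahead"
  ifelse(rightward == ahead, "right", "left")
}

direction_sign <- function(pursuit_direction) {
  ifelse(pursuit_direction == "rightward", 1,
         ifelse(pursuit_direction == "leftward", -1, 0))
}

# Reference flash is timed to the pursuit target's centre crossing (or to the
# equivalent moment of a fixation trial); the target flash follows at the SOA.
REFERENCE_FLASH_MS <- 1250

flash_times <- function(task, soa_ms) {
  ref <- if (task == "pursuit_absolute") NA_real_ else REFERENCE_FLASH_MS
  list(reference_ms = ref, target_ms = REFERENCE_FLASH_MS + soa_ms)
}

trial_duration_ms <- function(task) {
  if (task == "fixation_relative") 1750 else 2500
}
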