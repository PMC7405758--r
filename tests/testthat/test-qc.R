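test_that("clean pursuit at 10 deg/s yields no saccade events", {
  tr <- simulate_eye_trace(pursuit_cond(), quiet_observer(), seed = 1)
  expect_equal(nrow(detect_saccades(tr)), 0)
  trf <- simulate_eye_trace(fixation_cond(), quiet_observer(), seed = 1)
  expect_equal(nrow(detect_saccades(trf)), 0)
})

test_that("an injected step is detected as one event containing its onset", {
  tr <- simulate_eye_trace(pursuit_cond(), quiet_observer(), seed = 2)
  t0 <- 900
  x <- tr$x_deg
  x[tr$t_ms >= t0] <- x[tr$t_ms >= t0] + 1.5
  tr2 <- eye_trace(tr$t_ms, x, tr$valid, meta = trace_meta(tr))
  ev <- detect_saccades(tr2)
  expect_equal(nrow(ev), 1)
  expect_true(ev$onset_ms <= t0 && ev$offset_ms >= t0)
})

test_that("saccade detection hits generator ground truth on noisy traces", {
  o <- make_observer(4, vary = FALSE,
                     overrides = list(saccade_rate_hz = 0.8,
                                      blink_prob = 0.1))
  hits <- 0; truths <- 0; false_pos <- 0; detections <- 0
  for (s in 1:250) {
    tr <- simulate_eye_trace(pursuit_cond(), o, seed = s)
    truth <- trace_events(tr)
    sacc <- truth[truth$kind == "saccade", ]
    det <- detect_saccades(tr)
    truths <- truths + nrow(sacc)
    detections <- detections + nrow(det)
    for (i in seq_len(nrow(sacc))) {
      hits <- hits + any(det$onset_ms <= sacc$onset_ms[i] &
                           det$offset_ms >= sacc$onset_ms[i])
    }
    for (i in seq_len(nrow(det))) {
      false_pos <- false_pos +
        !any(sacc$onset_ms >= det$onset_ms[i] - 10 &
               sacc$onset_ms <= det$offset_ms[i] + 10)
    }
  }
  expect_gt(truths, 200)
  expect_gte(hits / truths, 0.95)
  expect_gte(1 - false_pos / detections, 0.95)
})

test_that("blink detection pads and merges invalid runs", {
  t_ms <- seq(0, 1998, by = 2)
  valid <- rep(TRUE, length(t_ms))
  expect_equal(nrow(detect_blinks(eye_trace(t_ms, rnorm(length(t_ms), 0,
                                                        0.02), valid))), 0)
  # one 60-ms run is covered with padding
  valid[t_ms >= 500 & t_ms <= 560] <- FALSE
  x <- rnorm(length(t_ms), 0, 0.02); x[!valid] <- NA
  ev <- detect_blinks(eye_trace(t_ms, x, valid))
  expect_equal(nrow(ev), 1)
  expect_lte(ev$onset_ms, 500); expect_gte(ev$offset_ms, 560)
  # two runs separated by 4 ms merge through the padding
  valid2 <- rep(TRUE, length(t_ms))
  valid2[t_ms >= 300 & t_ms <= 330] <- FALSE
  valid2[t_ms >= 336 & t_ms <= 366] <- FALSE
  x2 <- rnorm(length(t_ms), 0, 0.02); x2[!valid2] <- NA
  ev2 <- detect_blinks(eye_trace(t_ms, x2, valid2))
  expect_equal(nrow(ev2), 1)
})

test_that("gain is velocity over target speed, robust to masking", {
  tr <- simulate_eye_trace(pursuit_cond(), quiet_observer(), seed = 3)
  expect_equal(compute_gain(tr, 1250, 10), 1, tolerance = 1e-6)
  o <- make_observer(1, vary = FALSE,
                     overrides = list(pursuit_gain = 1.02, gain_sd = 0,
                                      saccade_rate_hz = 0, blink_prob = 0,
                                      trace_noise_deg = 0.005))
  tr2 <- simulate_eye_trace(pursuit_cond(), o, seed = 4)
  expect_equal(compute_gain(tr2, 1250, 10), 1.02, tolerance = 0.01)
  # leftward pursuit needs the signed target velocity
  trl <- simulate_eye_trace(pursuit_cond(200, "leftward", "ahead"), o,
                            seed = 4)
  expect_equal(compute_gain(trl, 1250, -10), 1.02, tolerance = 0.01)
  # stationary eye during nominal pursuit
  flat <- eye_trace(tr$t_ms, rep(0, nrow(tr)),
                    meta = list(pursuit_direction = "rightward",
                                target_speed = 10))
  expect_equal(compute_gain(flat, 1250, 10), 0, tolerance = 1e-9)
  expect_error(compute_gain(tr, 2480, 10), "beyond")
  # > 50% masked window
  half <- tr
  bad <- half$t_ms >= 1150 & half$t_ms <= 1350
  v <- half$valid; v[bad][1:80] <- FALSE
  x <- half$x_deg; x[!v] <- NA
  masked <- eye_trace(half$t_ms, x, v, meta = trace_meta(tr))
  expect_error(compute_gain(masked, 1250, 10), "masked")
})

test_that("the exclusion span is 400 ms at |SOA| 200 and 200 ms at 0", {
  expect_equal(exclusion_window_span(200), 400)
  expect_equal(exclusion_window_span(-200), 400)
  expect_equal(exclusion_window_span(0), 200)
})

test_that("trial exclusion applies deviation and event rules", {
  o <- quiet_observer()
  cond <- pursuit_cond(200, "rightward", "ahead")
  mk_trial <- function(id) {
    dplyr::bind_cols(cond, tibble::tibble(offset_deg = 0, subject = 1,
                                          trace_id = id))
  }
  clean <- simulate_eye_trace(cond, o, seed = 1)
  res <- exclude_trials(mk_trial("a"), list(a = clean))
  expect_true(res$qc_valid)

  # 2.5-deg deviation at the reference flash
  dev <- clean
  x <- dev$x_deg
  x[dev$t_ms >= 1230 & dev$t_ms <= 1270] <-
    x[dev$t_ms >= 1230 & dev$t_ms <= 1270] + 2.5
  # ramp edges create saccade-like velocity; test the deviation flag itself
  devtr <- eye_trace(dev$t_ms, x, dev$valid, meta = trace_meta(dev))
  res2 <- exclude_trials(mk_trial("a"), list(a = devtr))
  expect_true(res2$deviation_exceeded)
  expect_false(res2$qc_valid)

  # saccade 80 ms after the target flash (target at 1450 ms)
  sac <- clean
  xs <- sac$x_deg
  xs[sac$t_ms >= 1530] <- xs[sac$t_ms >= 1530] + 1.5
  sactr <- eye_trace(sac$t_ms, xs, sac$valid, meta = trace_meta(sac))
  res3 <- exclude_trials(mk_trial("a"), list(a = sactr))
  expect_true(res3$saccade_blink_near_flash)
  expect_false(res3$deviation_exceeded)

  # the same step 150 ms after the target flash does not exclude
  far <- clean
  xf <- far$x_deg
  xf[far$t_ms >= 1600] <- xf[far$t_ms >= 1600] + 1.5
  fartr <- eye_trace(far$t_ms, xf, far$valid, meta = trace_meta(far))
  expect_true(exclude_trials(mk_trial("a"), list(a = fartr))$qc_valid)

  # frame drops and missing traces
  fd <- mk_trial("a"); fd$frame_drop <- TRUE
  expect_false(exclude_trials(fd, list(a = clean))$qc_valid)
  expect_warning(resm <- exclude_trials(mk_trial("nope"), list(a = clean)),
                 "no matching trace")
  expect_true(resm$missing_trace)
  expect_false(resm$qc_valid)
})

test_that("exclusion is idempotent and order-independent", {
  o <- make_observer(2, vary = FALSE,
                     overrides = list(saccade_rate_hz = 1, blink_prob = 0.2))
  conds <- list(pursuit_cond(200, "rightward", "ahead"),
                pursuit_cond(-200, "leftward", "behind"),
                fixation_cond(0))
  trials <- purrr::map_dfr(1:30, function(i) {
    dplyr::bind_cols(conds[[1 + i %% 3]],
                     tibble::tibble(offset_deg = 0, subject = 1,
                                    trace_id = paste0("t", i)))
  })
  traces <- purrr::map(1:30, function(i) {
    simulate_eye_trace(conds[[1 + i %% 3]], o, seed = i)
  })
  names(traces) <- paste0("t", 1:30)
  once <- exclude_trials(trials, traces)
  twice <- exclude_trials(once, traces)
  expect_equal(once$qc_valid, twice$qc_valid)
  perm <- sample(30)
  shuffled <- exclude_trials(trials[perm, ], traces)
  expect_equal(shuffled$qc_valid, once$qc_valid[perm])
  rep <- qc_report(once)
  expect_equal(sum(rep$n_trials), 30)
  expect_equal(sum(rep$n_valid), sum(once$qc_valid))
})

test_that("exclusion decisions match a brute-force interval oracle", {
  o <- make_observer(6, vary = FALSE,
                     overrides = list(saccade_rate_hz = 1.5,
                                      blink_prob = 0.3,
                                      trace_noise_deg = 0.015))
  mismatches <- 0
  for (s in 1:120) {
    cond <- pursuit_cond(c(-200, 0, 200)[1 + s %% 3],
                         c("rightward", "leftward")[1 + s %% 2],
                         c("ahead", "behind")[1 + (s %/% 2) %% 2])
    tr <- simulate_eye_trace(cond, o, seed = 1000 + s)
    trial <- dplyr::bind_cols(cond, tibble::tibble(offset_deg = 0,
                                                   subject = 1,
                                                   trace_id = "x"))
    got <- exclude_trials(trial, list(x = tr))$saccade_blink_near_flash
    # oracle: ground-truth event intervals vs the two stimulus windows
    truth <- trace_events(tr)
    ref <- 1250; tgt <- 1250 + cond$soa_ms
    overlap <- function(on, off) {
      any(on <= c(ref, tgt) + 100 & off >= c(ref, tgt) - 100)
    }
    want <- nrow(truth) > 0 &&
      any(mapply(overlap, truth$onset_ms, truth$offset_ms))
    mismatches <- mismatches + (got != want)
  }
  # detection-based decisions may differ from ground truth only through
  # detector boundary effects; demand near-exact agreement
  expect_lte(mismatches, 3)
})
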