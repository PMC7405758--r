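make_relative_trials <- function(o, cond, offsets, n_each, seed) {
  sched <- dplyr::bind_cols(cond[rep(1, length(offsets) * n_each), ],
                            tibble::tibble(offset_deg = rep(offsets,
                                                            each = n_each)))
  pursuitloc:::simulate_relative_block(o, sched, seed = seed)
}

test_that("pooling conserves trials and mirrors hemifields", {
  o <- make_observer(1, vary = FALSE)
  fixL <- make_relative_trials(o, fixation_cond(0, "left"),
                               phase_grid("fixation_relative"), 10, 1)
  fixR <- make_relative_trials(o, fixation_cond(0, "right"),
                               phase_grid("fixation_relative"), 10, 2)
  trials <- dplyr::bind_rows(fixL, fixR)
  trials$subject <- 1
  binned <- pool_trials(trials, "fixation_relative")
  expect_equal(sum(binned$n), nrow(trials))          # conservation
  expect_equal(nrow(binned), 8)                      # L/R pooled per level
  expect_equal(sort(unique(binned$level)),
               phase_grid("fixation_relative"))

  # a left-hemifield "target not more rightward" key counts as more eccentric
  one <- fixL[1, ]; one$offset_deg <- -2.5; one$response_right <- 0L
  one$subject <- 1
  b1 <- pool_trials(one, "fixation_relative")
  expect_equal(b1$level, 2.5)
  expect_equal(b1$k, 1L)
})

test_that("fine-phase pooling unions the two grids per pursuit cell", {
  o <- make_observer(2, vary = FALSE)
  c1 <- pursuit_cond(200, "rightward", "ahead", phase = "fine1")
  c2 <- pursuit_cond(200, "rightward", "ahead", phase = "fine2")
  t1 <- make_relative_trials(o, c1, phase_grid("pursuit_relative", "fine1"),
                             3, 1)
  t2 <- make_relative_trials(o, c2,
                             1 + phase_grid("pursuit_relative", "fine2"),
                             3, 2)
  trials <- dplyr::bind_rows(t1, t2); trials$subject <- 1
  binned <- pool_trials(trials, "pursuit_relative")
  expect_setequal(binned$level, union(-4:4, 1 + seq(-2, 2, 0.5)))
  expect_equal(sum(binned$n), nrow(trials))
  # the coarse phase is excluded from the default pooling
  tc <- make_relative_trials(o, pursuit_cond(200, "rightward", "ahead",
                                             phase = "coarse"),
                             phase_grid("pursuit_relative", "coarse"), 2, 3)
  tc$subject <- 1
  expect_equal(sum(pool_trials(dplyr::bind_rows(trials, tc),
                               "pursuit_relative")$n), nrow(trials))
})

test_that("symmetric data yield a PSE at the mirror point", {
  lev <- seq(-2, 2, 0.5)
  k <- c(1, 3, 8, 20, 40, 60, 72, 77, 79)
  expect_identical(rev(80 - k), k)  # construction check: mirror-symmetric
  binned <- tibble::tibble(level = lev, k = k, n = 80)
  f <- fit_psychometric(binned)
  expect_true(f$converged)
  expect_equal(f$pse, 0, tolerance = 1e-6)
})

test_that("the PSE is equivariant to level translation and mirroring", {
  binned <- binned_from_truth(seq(-2, 2, 0.5), 60, 0.3, 0.8, seed = 4)
  f0 <- fit_psychometric(binned)
  shifted <- binned; shifted$level <- shifted$level + 1
  expect_equal(fit_psychometric(shifted)$pse, f0$pse + 1, tolerance = 1e-5)
  mirrored <- binned
  mirrored$level <- -mirrored$level
  mirrored$k <- mirrored$n - mirrored$k
  expect_equal(fit_psychometric(mirrored)$pse, -f0$pse, tolerance = 1e-4)
})

test_that("the MLE beats a coarse brute-force grid search", {
  binned <- binned_from_truth(seq(-2, 2, 0.5), 40, -0.4, 1.1,
                              guess = 0.02, lapse = 0.03, seed = 9)
  f <- fit_psychometric(binned)
  grid <- expand.grid(m = seq(-3, 3, 0.1), s = seq(0.2, 3, 0.1),
                      g = c(0, 0.03, 0.06), l = c(0, 0.03, 0.06))
  best_grid <- -min(vapply(seq_len(nrow(grid)), function(i) {
    pursuitloc:::neg_loglik_psy(
      c(grid$m[i], log(grid$s[i]), grid$g[i], grid$l[i]),
      binned$level, binned$k, binned$n)
  }, numeric(1)))
  expect_gte(f$loglik, best_grid - 1e-9)
  # fitted curve is non-decreasing
  xx <- seq(-5, 5, 0.01)
  expect_true(all(diff(psychometric_prob(xx, f$pse, f$sigma, f$guess,
                                         f$lapse)) >= 0))
})

test_that("degenerate and invalid inputs are handled honestly", {
  lev <- seq(-2, 2, 0.5)
  f <- suppressWarnings(fit_psychometric(tibble::tibble(level = lev, k = 0,
                                                        n = 40)))
  expect_false(f$converged)
  expect_equal(f$pse_ci95, c(-Inf, Inf))
  expect_error(fit_psychometric(tibble::tibble(level = 1:3, k = 1, n = 2)),
               "4 distinct")
  expect_error(fit_psychometric(tibble::tibble(level = lev, k = 99, n = 40)),
               "0 <= k <= n")
})

test_that("bootstrap CIs are deterministic, centred, and shrink with n", {
  binned <- binned_from_truth(seq(-2, 2, 0.5), 60, 0.75, 1,
                              guess = 0.02, lapse = 0.02, seed = 5)
  f <- fit_psychometric(binned)
  ci1 <- bootstrap_pse_ci(binned, f, n_boot = 199, seed = 7)
  expect_identical(ci1, bootstrap_pse_ci(binned, f, n_boot = 199, seed = 7))
  expect_true(ci1[1] < f$pse && f$pse < ci1[2])
  big <- binned_from_truth(seq(-2, 2, 0.5), 500, 0.75, 1,
                           guess = 0.02, lapse = 0.02, seed = 6)
  fb <- fit_psychometric(big)
  ci2 <- bootstrap_pse_ci(big, fb, n_boot = 199, seed = 7)
  expect_lt(diff(ci2), diff(ci1))
})

test_that("bootstrap CIs cover the generating PSE at roughly 95%", {
  covered <- 0
  for (r in 1:40) {
    binned <- binned_from_truth(seq(-2, 2, 0.5), 100, 0.4, 1,
                                guess = 0.02, lapse = 0.02, seed = 100 + r)
    f <- fit_psychometric(binned)
    if (!f$converged) next
    ci <- bootstrap_pse_ci(binned, f, n_boot = 199, seed = r)
    covered <- covered + (ci[1] <= 0.4 && 0.4 <= ci[2])
  }
  # 95% nominal; with 40 replicates allow generous sampling error
  expect_gte(covered, 33)
})

test_that("left/right averaging combines parameters and CIs", {
  b1 <- binned_from_truth(seq(-2, 2, 0.5), 80, 1.0, 0.9, seed = 11)
  b2 <- binned_from_truth(seq(-2, 2, 0.5), 80, 1.4, 1.1, seed = 12)
  f1 <- fit_psychometric(b1); f2 <- fit_psychometric(b2)
  f1$pse <- 1.0; f2$pse <- 1.4
  f1$pse_ci95 <- c(0.8, 1.2); f2$pse_ci95 <- c(1.1, 1.7)
  avg <- average_lr(f1, f2)
  expect_equal(avg$pse, 1.2)
  expect_equal(avg$sigma, mean(c(f1$sigma, f2$sigma)))
  expect_equal(avg$pse_ci95, c(0.8, 1.7))
  expect_identical(average_lr(f1, f1)$pse, f1$pse)
  pass <- average_lr(NULL, f2)
  expect_true(pass$one_sided)
  expect_equal(pass$pse, f2$pse)
  expect_error(average_lr(NULL, NULL), "missing")
})

test_that("averaging the two directions reduces estimation error", {
  o <- make_observer(3, vary = FALSE)
  wins <- 0
  for (r in 1:30) {
    cl <- pursuit_cond(200, "leftward", "ahead", phase = "fine2")
    cr <- pursuit_cond(200, "rightward", "ahead", phase = "fine2")
    truth <- true_pse(o, cr)
    grid <- truth + seq(-2, 2, 0.5)
    tl <- make_relative_trials(o, cl, to_eccentricity_axis(grid, "left"),
                               15, 200 + r)
    tr <- make_relative_trials(o, cr, grid, 15, 500 + r)
    trials <- dplyr::bind_rows(tl, tr); trials$subject <- 1
    binned <- pool_trials(trials, "pursuit_relative")
    fl <- fit_psychometric(binned[binned$pursuit_direction == "leftward", ])
    fr <- fit_psychometric(binned[binned$pursuit_direction == "rightward", ])
    avg <- average_lr(fl, fr)
    wins <- wins + (abs(avg$pse - truth) <=
                      max(abs(fl$pse - truth), abs(fr$pse - truth)))
  }
  expect_gte(wins, 15)
})
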