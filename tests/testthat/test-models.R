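test_that("the SOA-by-placement sign factor follows the shift table", {
  expect_equal(signed_condition_factor(200, "ahead"), 1)
  expect_equal(signed_condition_factor(200, "behind"), -1)
  expect_equal(signed_condition_factor(-200, "ahead"), -1)
  expect_equal(signed_condition_factor(-200, "behind"), 1)
  expect_equal(signed_condition_factor(0, "ahead"), 0)
  expect_error(signed_condition_factor(200, "sideways"), "placement")
})

test_that("compensation and retinal shifts reproduce the reference values", {
  expect_equal(compensation_shift(0.24, 200, 10, "ahead"), 0.48)
  expect_equal(compensation_shift(0.26, 200, 10, "behind"), -0.52)
  expect_equal(compensation_shift(0, 200, 10, "ahead"), 0)
  expect_equal(retinal_shift(200, 10, "ahead"), 2)
  expect_equal(retinal_shift(-200, 10, "ahead"), -2)
  expect_equal(retinal_shift(200, 10, "behind", fraction = 0.5), -1)
  expect_error(compensation_shift(0.2, 600, 10, "ahead"), "500")
  expect_error(retinal_shift(200, 10, "ahead", fraction = 2), "fraction")
})

test_that("shift antisymmetry holds in SOA sign and placement", {
  for (a in c(-0.3, 0, 0.17, 0.26)) {
    for (soa in c(-200, -100, 100, 200)) {
      expect_equal(compensation_shift(a, soa, 10, "ahead"),
                   -compensation_shift(a, -soa, 10, "ahead"))
      expect_equal(compensation_shift(a, soa, 10, "ahead"),
                   -compensation_shift(a, soa, 10, "behind"))
    }
  }
})

test_that("model predictions nest exactly", {
  expect_equal(predict_pse("A", 0.75, 200, "ahead"), 0.75)
  expect_equal(predict_pse("B", 0.75, 200, "ahead"), 2.75)
  expect_equal(predict_pse("D", 0, 200, "behind", a = 0.26), -2.52)
  withr::with_seed(8, {
    for (i in 1:25) {
      fx <- runif(1, -2, 2); a <- runif(1, -0.5, 0.8)
      soa <- sample(c(-200, 200, 150, -50), 1)
      pl <- sample(c("ahead", "behind"), 1)
      sp <- runif(1, 5, 20)
      comp <- compensation_shift(a, soa, sp, pl)
      ret <- retinal_shift(soa, sp, pl)
      expect_equal(predict_pse("D", fx, soa, pl, a, sp) -
                     predict_pse("B", fx, soa, pl, a, sp), comp)
      expect_equal(predict_pse("C", fx, soa, pl, a, sp) -
                     predict_pse("A", fx, soa, pl, a, sp), comp)
      expect_equal(predict_pse("B", fx, soa, pl, a, sp) -
                     predict_pse("A", fx, soa, pl, a, sp), ret)
    }
  })
  expect_error(predict_pse("C", 0, 200, "ahead"), "slope")
})

test_that("eccentricity regression recovers generating slopes", {
  o <- quiet_observer(ruler_noise_deg = 0.8)
  trials <- purrr::map_dfr(1:600, function(s) {
    soa <- c(-200, 0, 200)[1 + s %% 3]
    dir <- c("rightward", "leftward")[1 + s %% 2]
    pl <- c("ahead", "behind")[1 + (s %/% 2) %% 2]
    simulate_absolute_trial(o, absolute_cond(soa, dir, pl),
                            seed = 3000 + s, ruler_shifted = s %% 4 < 2)
  })
  trials$subject <- 1
  fit <- fit_eccentricity(decode_absolute_trials(trials))
  expect_lt(abs(fit$slope[fit$placement == "ahead"] - 0.24), 0.06)
  expect_lt(abs(fit$slope[fit$placement == "behind"] - 0.26), 0.06)
  expect_true(all(fit$n_points == 300))
})

test_that("noiseless eccentricity data are fit exactly", {
  # two noiseless points per placement -> exact interpolating line
  df <- tibble::tibble(
    subject = 1, placement = rep(c("ahead", "behind"), each = 2),
    hemifield = "right", target_deg = 7.5,
    perceived_deg = c(7.5 + 0.95 + 0.24 * c(5.5, 9.5),
                      7.5 - 2.9 + 0.26 * c(5.5, 9.5)),
    eye_at_flash_deg = c(2, -2, 2, -2))
  fit <- fit_eccentricity(df)
  expect_equal(fit$slope, c(0.24, 0.26), tolerance = 1e-12)
  expect_equal(fit$intercept, c(0.95, -2.9), tolerance = 1e-12)
  # zero mislocalization everywhere -> zero line
  df0 <- df; df0$perceived_deg <- 7.5
  fit0 <- fit_eccentricity(df0)
  expect_equal(fit0$slope, c(0, 0))
  expect_equal(fit0$intercept, c(0, 0))
  # a single eccentricity level leaves the slope undefined
  df1 <- df; df1$eye_at_flash_deg <- 0
  expect_error(fit_eccentricity(df1), "single eccentricity")
})

test_that("model evaluation matches closed-form least squares", {
  ev <- evaluate_model(1:5, 1:5)
  expect_equal(ev$slope, 1)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$d_mean, 0)
  ev1 <- evaluate_model(1:5 + 1, 1:5)
  expect_equal(ev1$slope, 1)
  expect_equal(ev1$d_mean, 1 / sqrt(2))
  expect_equal(evaluate_model(1:5 + 1, 1:5, distance = "vertical")$d_mean, 1)

  withr::with_seed(13, {
    for (i in 1:20) {
      m <- rnorm(8); p <- rnorm(8)
      ev2 <- evaluate_model(p, m)
      # brute-force oracle from the normal equations
      slope <- sum((m - mean(m)) * (p - mean(p))) / sum((m - mean(m))^2)
      r <- sum(scale(m) * scale(p)) / 7
      d <- abs(p - m) / sqrt(2)
      expect_equal(ev2$slope, slope, tolerance = 1e-9)
      expect_equal(ev2$pearson_r, r, tolerance = 1e-9)
      expect_equal(ev2$d_mean, mean(d), tolerance = 1e-9)
      expect_equal(ev2$d_sd, sd(d), tolerance = 1e-9)
      # invariance under simultaneous permutation
      perm <- sample(8)
      expect_equal(evaluate_model(p[perm], m[perm])$d_mean, ev2$d_mean)
    }
  })
  expect_error(evaluate_model(1:2, 1:2), "3 matched")
  expect_error(evaluate_model(1:4, rep(1, 4)), "zero variance")
})

test_that("model ranking orders by distance then slope", {
  evs <- tibble::tibble(model = c("A", "B", "C", "D"),
                        slope = c(0.21, 1.74, 0.92, 2.45),
                        d_mean = c(2.38, 2.23, 0.25, 4.37))
  expect_equal(select_model(evs)$model, c("C", "B", "A", "D"))
  one <- evs[1, ]
  expect_equal(select_model(one)$model, "A")
  ties <- tibble::tibble(model = c("x", "y"), slope = c(1.2, 0.8),
                         d_mean = c(1, 1))
  expect_equal(select_model(ties)$model, c("x", "y"))  # stable input order
})
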