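test_that("stability stats: sigma and rolling series behave on closed forms", {
  rec <- empty_records_for_test(200)
  st <- stability_stats(rec, window = 10)
  expect_equal(unname(st$sigma_nm), c(0, 0, 0))
  expect_equal(st$rolling$x$mean, rep(0, 200))

  # alternating +-1: sd = 1 (n large), rolling mean ~ 0 for even windows
  rec$e_x <- rep(c(1, -1), 100)
  st2 <- stability_stats(rec, window = 10)
  expect_equal(st2$sigma_nm[["x"]], stats::sd(rec$e_x))
  interior <- st2$rolling$x$mean[6:194]
  expect_lt(max(abs(interior)), 1e-12)
  expect_equal(nrow(st2$rolling$x), 200)

  # sampling distribution check at n = 10000
  rec3 <- empty_records_for_test(10000)
  rec3$e_x <- with_seed_test(99, stats::rnorm(10000))
  st3 <- stability_stats(rec3, window = 1000)
  expect_lt(abs(st3$sigma_nm[["x"]] - 1), 0.05)

  expect_error(stability_stats(rec[0, ]), "empty")
})

test_that("sigma is order-invariant but the rolling series is not", {
  rec <- empty_records_for_test(500)
  rec$e_x <- with_seed_test(7, cumsum(stats::rnorm(500)))
  shuffled <- rec
  shuffled$e_x <- with_seed_test(8, sample(rec$e_x))
  a <- stability_stats(rec, window = 50)
  b <- stability_stats(shuffled, window = 50)
  expect_equal(a$sigma_nm[["x"]], b$sigma_nm[["x"]])
  expect_false(isTRUE(all.equal(a$rolling$x$mean, b$rolling$x$mean)))
})

test_that("invalid samples are excluded from sigma", {
  rec <- empty_records_for_test(100)
  rec$e_x <- rep(1, 100)
  rec$e_x[51:100] <- 1000
  rec$valid_x[51:100] <- FALSE
  st <- stability_stats(rec, window = 10)
  expect_equal(st$sigma_nm[["x"]], 0)
})

test_that("step-response fit recovers exact and noisy synthetic parameters", {
  rec <- synth_step_response_log(alpha = 20, t0 = 2, tau = 5,
                                 noise_sd_nm = 0)
  f <- fit_step_response(rec, axis = "x")
  expect_equal(f$alpha, 20, tolerance = 1e-6)
  expect_equal(f$t0, 2, tolerance = 1e-6)
  expect_equal(f$tau, 5, tolerance = 1e-6)
  expect_lt(f$residual_rms, 1e-9)
  expect_equal(f$n_steps_averaged, 20)

  rec2 <- synth_step_response_log(alpha = 20, t0 = 2, tau = 5,
                                  noise_sd_nm = 0.3, n_steps = 10, seed = 3)
  f2 <- fit_step_response(rec2, axis = "x")
  expect_lt(abs(f2$tau - 5), 0.5)

  # flat response: nothing to fit
  flat <- synth_step_response_log(alpha = 0, noise_sd_nm = 0)
  expect_error(fit_step_response(flat, axis = "x"), "flat")
})

test_that("step-response parameter recovery holds over randomized truths", {
  set.seed(14)
  rel_err <- replicate(25, {
    tau <- runif(1, 3, 8)
    rec <- synth_step_response_log(alpha = runif(1, 10, 30),
                                   t0 = runif(1, 1, 4), tau = tau,
                                   noise_sd_nm = 0.3,
                                   seed = sample.int(1e6, 1))
    f <- fit_step_response(rec, axis = "x")
    abs(f$tau - tau) / tau
  })
  expect_lt(stats::median(rel_err), 0.1)
})

test_that("staircase calibration inverts an injected estimator gain", {
  rec <- synth_staircase_log(gain = 0.9, noise_sd_nm = 0.5, seed = 21)
  cal <- calibrate(rec, axis = "x")
  expect_equal(cal$scale, 1 / 0.9, tolerance = 0.02)
  expect_true(cal$ci[1] < cal$ci[2])

  # ideal estimator: scale 1
  rec1 <- synth_staircase_log(gain = 1, noise_sd_nm = 0.2, seed = 22)
  expect_equal(calibrate(rec1, axis = "x")$scale, 1, tolerance = 0.02)

  # drift-contaminated staircase still calibrates (per-plateau detrend)
  rec_d <- synth_staircase_log(gain = 0.9, noise_sd_nm = 0.5,
                               drift_nm_per_iter = 0.05, seed = 23)
  expect_equal(calibrate(rec_d, axis = "x")$scale, 1 / 0.9,
               tolerance = 0.05)

  expect_error(calibrate(rec, axis = "x", commanded_step_nm = 0),
               "nonzero")
  noise_only <- synth_staircase_log(gain = 1e-6, noise_sd_nm = 2, seed = 24)
  expect_error(calibrate(noise_only, axis = "x"), "indistinguishable")
})

test_that("drift reduction factors come from mean-centered rms ratios", {
  tr <- data.frame(t = 1:100,
                   x_nm = sin(1:100 / 7), y_nm = cos(1:100 / 9),
                   z_nm = sin(1:100 / 5) + 3)
  same <- drift_reduction(tr, tr)
  expect_equal(unname(same$factors), c(1, 1, 1))

  tr10 <- tr
  tr10[c("x_nm", "y_nm", "z_nm")] <- 10 * tr[c("x_nm", "y_nm", "z_nm")]
  ten <- drift_reduction(tr, tr10)
  expect_equal(unname(ten$factors), c(10, 10, 10), tolerance = 1e-12)

  still <- tr
  still[c("x_nm", "y_nm", "z_nm")] <- 0
  lb <- drift_reduction(still, tr)
  expect_true(all(lb$lower_bound))
  expect_true(all(is.na(lb$factors)))

  expect_error(drift_reduction(tr, tr[1:50, ]), "equal duration")
})
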