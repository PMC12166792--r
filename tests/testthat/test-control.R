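test_that("controller update implements PI with double integrator and clamps", {
  g <- controller_gains(kp = 1, ki = 0, kii = 0)
  st <- controller_state()
  upd <- controller_update(c(x = 0, y = 0, z = 0), st, g)
  expect_equal(upd$correction_nm, c(x = 0, y = 0, z = 0))
  upd <- controller_update(c(x = 10, y = 0, z = 0), st, g)
  expect_equal(upd$correction_nm[["x"]], -10)

  # closed-form discrete sums for constant error
  g2 <- controller_gains(kp = 0.5, ki = 0.1, kii = 0)
  st2 <- controller_state()
  for (k in 1:50) {
    upd2 <- controller_update(c(x = 2, y = 0, z = 0), st2, g2)
    st2 <- upd2$state
  }
  expect_equal(st2$integral[["x"]], 100)          # 50 * 2
  expect_equal(st2$double_integral[["x"]], sum(2 * (1:50)))
  expect_equal(upd2$correction_nm[["x"]], -(0.5 * 2 + 0.1 * 100))

  # output clamp
  g3 <- controller_gains(kp = 10, output_limit_nm = 15)
  upd3 <- controller_update(c(x = 10, y = 0, z = 0), controller_state(), g3)
  expect_equal(upd3$correction_nm[["x"]], -15)
})

test_that("invalid axes freeze integrators and produce zero correction", {
  g <- controller_gains(kp = 1, ki = 1, kii = 0)
  err <- structure(list(e_nm = c(x = NA_real_, y = 3, z = NA_real_),
                        valid = c(x = FALSE, y = TRUE, z = FALSE),
                        fits = list()), class = "error_signal")
  upd <- controller_update(err, controller_state(), g)
  expect_equal(upd$correction_nm[["x"]], 0)
  expect_equal(upd$state$integral[["x"]], 0)
  expect_equal(upd$correction_nm[["y"]], -(3 + 3))
  # a non-finite error on a *valid* axis is an estimator fault
  bad <- err
  bad$valid[["x"]] <- TRUE
  expect_error(controller_update(bad, controller_state(), g), "non-finite")
})

test_that("controller sign convention opposes the measured displacement", {
  g <- controller_gains(kp = 0.6, ki = 0.05, kii = 0.001)
  upd <- controller_update(c(x = 5, y = -5, z = 2), controller_state(), g)
  expect_lt(upd$correction_nm[["x"]], 0)
  expect_gt(upd$correction_nm[["y"]], 0)
  expect_lt(upd$correction_nm[["z"]], 0)
})

test_that("default gains keep a 2000-iteration drifting loop bounded and unbiased", {
  # pure numeric plant: displacement accumulates drift plus corrections
  g <- controller_gains()
  st <- controller_state()
  d <- c(x = 0, y = 0, z = 0)
  drift <- c(x = 0.3, y = -0.2, z = 0.1)
  e_hist <- matrix(NA_real_, 2000, 3)
  for (k in 1:2000) {
    d <- d + drift
    e_hist[k, ] <- d          # the error the estimator would measure
    upd <- controller_update(d, st, g)
    st <- upd$state
    d <- d + upd$correction_nm
  }
  expect_lt(max(abs(e_hist[500:2000, ])), 1)          # no growing oscillation
  expect_lt(max(abs(colMeans(e_hist[500:2000, ]))), 0.05)  # ramp rejected
})

test_that("engage acquires setpoint plus one frame per plane and returns to start", {
  eng <- noiseless_engage()
  expect_equal(eng$session$exposures, 3 * 11 + 1)
  expect_equal(unname(eng$session$stage$commanded_nm), c(0, 0, 0))
  expect_equal(unname(true_position(eng$session$stage)), c(0, 0, 0))
  expect_equal(unname(eng$state$integral), c(0, 0, 0))
})

test_that("zero drift and zero noise keep the loop stationary", {
  eng <- noiseless_engage()
  run <- run_closed_loop(eng, 15)
  expect_lt(max(abs(run$records[, c("e_x", "e_y", "e_z")])), 1.5)
  expect_lt(max(abs(run$records[, c("true_x", "true_y", "true_z")])), 2)
})

test_that("with all gains zero the stage never moves and errors track the drift", {
  drift <- drift_model("linear", rate_nm_per_iter = c(0.5, 0, 0))
  cfg <- stab_config(gains = controller_gains(kp = 0, ki = 0, kii = 0))
  ses <- sim_session(test_scene(), drift = drift, seed = 6)
  eng <- engage(ses, cfg)
  run <- run_closed_loop(eng, 40)
  expect_true(all(run$records$cmd_x == 0))
  # open-loop error reproduces the drift track (modulo estimator gain)
  fit <- stats::lm(e_x ~ true_x, data = run$records)
  expect_gt(stats::coef(fit)[2], 0.7)
  expect_gt(stats::cor(run$records$e_x, run$records$true_x), 0.99)
})

test_that("identical seeds and config give bit-identical loop records", {
  mk <- function() {
    drift <- drift_model("random_walk", sigma_nm = c(0.3, 0.3, 0.3),
                         seed = 11)
    ses <- sim_session(test_scene(), noise = noise_model(), drift = drift,
                       seed = 33)
    run_closed_loop(engage(ses, stab_config(seed = 33)), 12)
  }
  r1 <- mk()$records
  r2 <- mk()$records
  expect_identical(r1, r2)
})
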