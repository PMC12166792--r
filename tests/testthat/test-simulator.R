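test_that("holey-carbon geometry puts hole centers on the expected lattice", {
  sc <- virtual_scene(field_px = c(96, 96), pixel_size_nm = c(75, 75),
                      supersample = 4)
  # 2 um holes with 2 um spacing: centers every 4 um = 53.3 px at 75 nm
  expect_equal(sc$hole_pitch_nm / 75, 53.3, tolerance = 0.01)
  m <- render_scene(sc)
  expect_equal(dim(m), c(384, 384))
  # dark hole at the field center, bright film in between
  ctr <- m[192, 192]
  mid <- m[192, 192 + round(sc$hole_pitch_nm / 2 / (75 / 4))]
  expect_lt(ctr, mid)
  # bimodal-ish: both levels present in quantity
  lvl <- range(m)
  expect_gt(mean(m < lvl[1] + 0.1 * diff(lvl)), 0.05)
  expect_gt(mean(m > lvl[2] - 0.1 * diff(lvl)), 0.3)
})

test_that("bead field with zero beads renders uniform background", {
  sc <- virtual_scene("bead_field", field_px = c(16, 16), n_beads = 0,
                      bead_positions = matrix(numeric(0), 0, 2))
  m <- render_scene(sc)
  expect_equal(max(m) - min(m), 0)
  expect_equal(m[1, 1], sc$background)
})

test_that("scenes and frames are deterministic given seeds", {
  s1 <- virtual_scene("bead_field", field_px = c(32, 32), n_beads = 10,
                      seed = 5)
  s2 <- virtual_scene("bead_field", field_px = c(32, 32), n_beads = 10,
                      seed = 5)
  expect_identical(render_scene(s1), render_scene(s2))
  set.seed(4); f1 <- image_at(s1, c(5, 3, 10), noise = noise_model())
  set.seed(4); f2 <- image_at(s2, c(5, 3, 10), noise = noise_model())
  expect_identical(unclass(f1), unclass(f2))
})

test_that("features smaller than the render resolution are rejected", {
  expect_error(virtual_scene("bead_field", bead_sigma_nm = 10),
               "supersampled")
})

test_that("defocus is symmetric about focus and broadens monotonically", {
  sc <- test_scene(field = 64, defocus_nm = 0)
  up <- sorted_profile(normalize_frame(image_at(sc, c(0, 0, 150))))
  dn <- sorted_profile(normalize_frame(image_at(sc, c(0, 0, -150))))
  expect_equal(as.numeric(up), as.numeric(dn), tolerance = 1e-12)

  sc2 <- test_scene(field = 64, defocus_nm = 2000)
  p0 <- sorted_profile(normalize_frame(image_at(sc2, c(0, 0, 0))))
  p20 <- sorted_profile(normalize_frame(image_at(sc2, c(0, 0, 20))))
  p200 <- sorted_profile(normalize_frame(image_at(sc2, c(0, 0, 200))))
  expect_gt(profile_mse(p0, p200), profile_mse(p0, p20))
})

test_that("histogram sensitivity to z is larger at moderate defocus than in focus", {
  adj <- function(defoc) {
    sc <- test_scene(field = 64, defocus_nm = defoc)
    a <- sorted_profile(normalize_frame(image_at(sc, c(0, 0, 0))))
    b <- sorted_profile(normalize_frame(image_at(sc, c(0, 0, 20))))
    stats::var(as.numeric(a) - as.numeric(b))
  }
  expect_gt(adj(2500), adj(0))
})

test_that("lateral shifts out of the simulated range error out", {
  sc <- test_scene(field = 64)
  expect_error(image_at(sc, c(9000, 0, 0)), "outside simulated range")
})

test_that("stage follows commands, accumulates drift, and clamps at travel", {
  st <- stage_state()
  st <- stage_step(st, c(20, 0, 0))
  expect_equal(unname(true_position(st)), c(20, 0, 0))

  drift <- drift_model("linear", rate_nm_per_iter = c(1, 0, 0))
  st2 <- stage_state()
  for (k in 1:100) st2 <- stage_step(st2, c(0, 0, 0), drift)
  expect_equal(unname(true_position(st2)), c(100, 0, 0))

  st3 <- stage_state(travel_limit_nm = 50)
  expect_warning(st3 <- stage_step(st3, c(100, 0, 0)), "clamped")
  expect_true(st3$clamped)
  expect_equal(st3$commanded_nm[["x"]], 50)

  # first-order settle approaches the command monotonically
  st4 <- stage_state(settle_alpha = 0.5)
  gaps <- numeric(5)
  for (k in 1:5) {
    st4 <- stage_step(st4, c(10, 0, 0))
    gaps[k] <- abs(st4$commanded_nm[["x"]] - st4$actual_nm[["x"]])
  }
  expect_true(all(diff(gaps) < 0))
})

test_that("random-walk drift has the configured increment variance", {
  drift <- drift_model("random_walk", sigma_nm = c(0.5, 0.5, 0.5), seed = 2)
  inc <- t(vapply(1:1000, function(k) drift_increment(drift, k), numeric(3)))
  v <- apply(inc, 2, stats::var)
  expect_true(all(abs(v - 0.25) / 0.25 < 0.15))
  # deterministic given (seed, iteration)
  expect_identical(drift_increment(drift, 17), drift_increment(drift, 17))
})

test_that("simulated reference stacks cover the range with the right entry kinds", {
  ses <- sim_session(test_scene(field = 64), seed = 9)
  res <- acquire_reference_stack_sim(ses, axis_stack_config("z"))
  expect_length(res$stack$entries, 11)
  expect_equal(res$stack$positions_nm, seq(-100, 100, 20))
  expect_s3_class(res$stack$entries[[1]], "sorted_profile")
  res_x <- acquire_reference_stack_sim(res$session, axis_stack_config("x"))
  expect_true(is.matrix(res_x$stack$entries[[1]]))
})

test_that("staircase protocol logs the expected number of disturbance events", {
  eng <- noiseless_engage()
  cfg0 <- eng$config
  cfg0$gains <- controller_gains(kp = 0, ki = 0, kii = 0)
  open <- eng; open$config <- cfg0
  st <- staircase_protocol(open, axis = "x", step_nm = 20,
                           period_iters = 5, n_cycles = 2)
  ev <- attr(st$records, "disturbance_events")
  expect_equal(nrow(ev), 8)
  expect_equal(sum(ev$direction == 1), 4)
  expect_setequal(unique(st$records$dist_x), c(0, 20, -20))
  # feedback off: the error reproduces the square wave
  r <- st$records
  hi <- r$e_x[r$dist_x == 20]
  lo <- r$e_x[r$dist_x == 0]
  expect_gt(mean(hi) - mean(lo), 14)
  expect_warning(staircase_protocol(open, axis = "x", step_nm = 150,
                                    period_iters = 2, n_cycles = 1),
                 "rail")
})
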