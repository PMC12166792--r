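make_lateral_stack <- function(n_planes = 7, nr = 8, nc = 8, seed = 3) {
  set.seed(seed)
  entries <- lapply(seq_len(n_planes), function(i) {
    normalize_frame(random_frame(nr, nc))
  })
  positions <- (seq_len(n_planes) - (n_planes + 1) / 2) * 20
  reference_stack("x", entries, positions)
}

test_that("reference stack validates spacing, center and normalization", {
  st <- make_lateral_stack()
  expect_s3_class(st, "reference_stack")
  expect_equal(st$center_index, 4)
  expect_equal(st$step_nm, 20)
  expect_error(reference_stack("x", st$entries, rev(st$positions_nm)),
               "increasing")
  expect_error(reference_stack("x", st$entries, st$positions_nm + 5),
               "zero")
  raw <- lapply(st$entries, function(e) {
    a <- unclass(e); attr(a, "normalized") <- NULL; a
  })
  expect_error(reference_stack("x", raw, st$positions_nm), "normalized")
})

test_that("axis stack config enforces odd plane counts and yields symmetric positions", {
  cfg <- axis_stack_config("z", range_nm = 200, step_nm = 20)
  expect_equal(cfg$n_planes, 11)
  expect_equal(stack_positions(cfg), seq(-100, 100, 20))
  expect_error(axis_stack_config("z", range_nm = 100, step_nm = 40),
               "integer")
  expect_error(axis_stack_config("z", range_nm = 60, step_nm = 20),
               "odd")
})

test_that("a frame matching one stack plane peaks there in the scaled curve", {
  st <- make_lateral_stack(n_planes = 9)
  for (k in c(2, 5, 8)) {
    curve <- build_match_curve(st$entries[[k]], st)
    expect_equal(which.max(curve$scaled), k)
    expect_equal(range(curve$scaled), c(0, 1))
    expect_length(curve$raw, 9)
  }
})

test_that("z match curves use MSE, invert, and are zero only at the source plane", {
  set.seed(4)
  frames <- lapply(1:7, function(i) normalize_frame(random_frame(10, 10)))
  entries <- lapply(frames, sorted_profile)
  st <- reference_stack("z", entries, seq(-60, 60, 20))
  curve <- build_match_curve(frames[[4]], st)
  expect_identical(curve$metric, "mse")
  expect_equal(curve$raw[4], 0)
  expect_true(all(curve$raw[-4] > 0))
  expect_equal(which.max(curve$scaled), 4)  # inversion flips min to max
})

test_that("flat match curves are rejected", {
  st <- make_lateral_stack()
  same <- st
  same$entries <- rep(st$entries[1], length(st$entries))
  expect_error(build_match_curve(st$entries[[1]], same), "flat")
})

test_that("Gaussian peak fit recovers exact parameters and flags boundary peaks", {
  u <- 0:10
  y <- 1 * exp(-(u - 5.3)^2 / (2 * 2^2))
  fit <- fit_gaussian_peak(y)
  expect_true(fit$converged)
  # curve indices are 1-based in R: mu = 5.3 on a 0-based axis is 6.3 here
  expect_equal(fit$center_index, 6.3, tolerance = 1e-6)
  expect_equal(fit$width, 2, tolerance = 1e-4)

  # symmetry forces the center onto the symmetric point
  ys <- c(0, 0.2, 0.7, 1, 0.7, 0.2, 0)
  fs <- fit_gaussian_peak(ys)
  expect_equal(fs$center_index, 4, tolerance = 1e-6)

  # strictly monotone curve: no interior peak
  expect_error(fit_gaussian_peak(seq(0, 1, length.out = 11)),
               "out of stack range")
  expect_error(fit_gaussian_peak(seq(1, 0, length.out = 11)),
               "out of stack range")
})

test_that("fitted peak index converts to nm against the stack center", {
  st <- make_lateral_stack(n_planes = 11)  # center_index 6, step 20
  fit <- list(center_index = 6, converged = TRUE)
  expect_equal(index_to_nm(fit, st), 0)
  fit$center_index <- 7
  expect_equal(index_to_nm(fit, st), 20)
  fit$center_index <- 5.5
  expect_equal(index_to_nm(fit, st), -10)
  fit$converged <- FALSE
  expect_error(index_to_nm(fit, st), "non-converged")
})
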