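# shared virtual-microscope fixtures; heavy objects (engaged loops) are
# built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

test_scene <- function(field = 128L, defocus_nm = 2000, ...) {
  virtual_scene(field_px = c(field, field), pixel_size_nm = c(75, 78),
                defocus_nm = defocus_nm, ...)
}

# engaged loop on a noiseless holey-carbon scene, shared across tests
noiseless_engage <- function() {
  if (is.null(.fixtures$noiseless)) {
    ses <- sim_session(test_scene(), seed = 42L)
    .fixtures$noiseless <- engage(ses, stab_config(seed = 42L))
  }
  .fixtures$noiseless
}

# staircase-calibrated per-axis factors for the shared noiseless engage
noiseless_calibration <- function() {
  if (is.null(.fixtures$noiseless_cal)) {
    .fixtures$noiseless_cal <- staircase_calibration(noiseless_engage())
  }
  .fixtures$noiseless_cal
}

# staircase-calibrated per-axis factors for an engaged loop (feedback off)
staircase_calibration <- function(engaged, period_iters = 6L, n_cycles = 3L) {
  cfg0 <- engaged$config
  cfg0$gains <- controller_gains(kp = 0, ki = 0, kii = 0)
  open <- engaged
  open$config <- cfg0
  vapply(c(x = "x", y = "y", z = "z"), function(ax) {
    st <- staircase_protocol(open, axis = ax, step_nm = 20,
                             period_iters = period_iters, n_cycles = n_cycles)
    calibrate(st$records, axis = ax)$scale
  }, numeric(1))
}

random_frame <- function(nr, nc) {
  matrix(stats::runif(nr * nc), nr, nc)
}

empty_records_for_test <- function(n) nanolock:::empty_records(n)

with_seed_test <- function(seed, expr) nanolock:::with_seed(seed, expr)
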