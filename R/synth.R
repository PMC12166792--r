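#' Synthesize an idealized staircase calibration log
#'
#' Generates the error-signal log an estimator with a fixed gain would
#' record during a feedback-off staircase: the true stage offset toggles
#' between 0 and `step_nm` every `period_iters` iterations, and the
#' recorded error is `gain * true offset` plus linear drift and Gaussian
#' estimator noise. Used to validate [calibrate()] against a known
#' injected gain without running the full imaging simulator.
#'
#' @param gain Injected estimator gain (true calibration factor is
#'   `1/gain`).
#' @param step_nm Staircase amplitude, nm.
#' @param period_iters Iterations per plateau.
#' @param n_steps Steps in each direction.
#' @param noise_sd_nm Estimator noise sd, nm.
#' @param drift_nm_per_iter Linear drift rate contaminating the log.
#' @param axis Axis label for the generated columns.
#' @param seed RNG seed.
#' @return Loop-record data frame with a `disturbance_events` attribute,
#'   directly consumable by [calibrate()].
#' @export
synth_staircase_log <- function(gain = 1, step_nm = 20, period_iters = 25,
                                n_steps = 10, noise_sd_nm = 1,
                                drift_nm_per_iter = 0, axis = "x",
                                seed = 1L) {
  n_segments <- 2L * n_steps + 1L
  n <- n_segments * period_iters
  k <- seq_len(n)
  seg <- (k - 1L) %/% period_iters
  level <- ifelse(seg %% 2L == 1L, step_nm, 0)
  e <- with_seed(seed,
                 gain * level + drift_nm_per_iter * k +
                   stats::rnorm(n, sd = noise_sd_nm))
  records <- empty_records(n)
  records[[paste0("e_", axis)]] <- e
  records[[paste0("valid_", axis)]] <- TRUE
  records[[paste0("dist_", axis)]] <- level
  events <- data.frame(iter = seq(period_iters + 1L, by = period_iters,
                                  length.out = 2L * n_steps),
                       direction = rep(c(1, -1), n_steps))
  attr(records, "disturbance_events") <- events
  attr(records, "staircase") <- list(axis = axis, step_nm = step_nm,
                                     period_iters = period_iters,
                                     n_steps = n_steps)
  records
}

#' Synthesize a step-response log with known dynamics
#'
#' Generates error signals that follow the delayed-exponential response
#' model (`alpha` held until dead time `t0`, then decaying with constant
#' `tau`) after each of `2 * n_steps` alternating disturbances, plus
#' Gaussian noise. Used to validate [fit_step_response()] parameter
#' recovery.
#'
#' @param alpha Step amplitude, nm.
#' @param t0 Dead time, iterations.
#' @param tau Decay constant, iterations.
#' @param period_iters Iterations between disturbances.
#' @param n_steps Steps in each direction.
#' @param noise_sd_nm Noise sd, nm.
#' @param axis Axis label.
#' @param seed RNG seed.
#' @return Loop-record data frame with a `disturbance_events` attribute.
#' @export
synth_step_response_log <- function(alpha = 20, t0 = 2, tau = 5,
                                    period_iters = 40, n_steps = 10,
                                    noise_sd_nm = 0.3, axis = "x",
                                    seed = 1L) {
  n_events <- 2L * n_steps
  n <- (n_events + 1L) * period_iters
  events <- data.frame(iter = seq(period_iters + 1L, by = period_iters,
                                  length.out = n_events),
                       direction = rep(c(1, -1), n_steps))
  e <- numeric(n)
  for (j in seq_len(n_events)) {
    tt <- 0:(period_iters - 1L)
    resp <- alpha * exp(-pmax(tt - t0, 0) / tau)
    idx <- events$iter[j] + tt
    idx_ok <- idx <= n
    e[idx[idx_ok]] <- e[idx[idx_ok]] + events$direction[j] * resp[idx_ok]
  }
  e <- e + with_seed(seed, stats::rnorm(n, sd = noise_sd_nm))
  records <- empty_records(n)
  records[[paste0("e_", axis)]] <- e
  records[[paste0("valid_", axis)]] <- TRUE
  attr(records, "disturbance_events") <- events
  records
}

empty_records <- function(n) {
  records <- data.frame(iter = seq_len(n), t_s = seq_len(n))
  for (ax in AXES) {
    records[[paste0("e_", ax)]] <- 0
    records[[paste0("valid_", ax)]] <- TRUE
    records[[paste0("cmd_", ax)]] <- 0
    records[[paste0("true_", ax)]] <- 0
    records[[paste0("dist_", ax)]] <- 0
    records[[paste0("fitrms_", ax)]] <- NA_real_
  }
  records
}
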