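#' Controller gains for the stabilization loop
#'
#' Discrete-time proportional-integral control with a small second-order
#' integrator: per iteration and per axis the correction is
#' `-(kp * e + ki * I + kii * II)` where `I` is the running sum of errors
#' and `II` the running sum of `I`. The double integrator helps against
#' persistent, slowly accelerating drifts (e.g. thermal); it must stay a
#' small fraction of `ki` or it destabilizes the loop. Gains are per
#' iteration (the loop is iteration-clocked, no dt scaling).
#'
#' Defaults were chosen on the virtual microscope for settling within
#' about 5 iterations after a step with no more than ~30% overshoot.
#'
#' @param kp,ki,kii Non-negative dimensionless gains.
#' @param output_limit_nm Per-iteration actuation clamp, nm.
#' @param stage_limit_nm Absolute stage travel bound, nm; the integrators
#'   are also clamped here (anti-windup).
#' @return List of class `controller_gains`.
#' @export
controller_gains <- function(kp = 0.6, ki = 0.05, kii = 0.001,
                             output_limit_nm = 100,
                             stage_limit_nm = 50000) {
  stopifnot(kp >= 0, ki >= 0, kii >= 0,
            output_limit_nm > 0, stage_limit_nm > 0)
  structure(list(kp = kp, ki = ki, kii = kii,
                 output_limit_nm = output_limit_nm,
                 stage_limit_nm = stage_limit_nm),
            class = "controller_gains")
}

#' Fresh (zeroed) controller state
#' @return List of class `controller_state` with per-axis `integral`,
#'   `double_integral` and `last_command_nm`, all zero.
#' @export
controller_state <- function() {
  z <- c(x = 0, y = 0, z = 0)
  structure(list(integral = z, double_integral = z, last_command_nm = z),
            class = "controller_state")
}

#' One controller update
#'
#' Valid axes accumulate `integral += e`, `double_integral += integral`
#' and emit `-(kp e + ki I + kii II)` clamped to the per-iteration output
#' limit. Axes flagged invalid (failed fit) produce zero correction and
#' leave their integrators frozen, so a transient estimator fault does not
#' kick the stage. Non-finite error values on a valid axis indicate an
#' estimator fault upstream and are rejected.
#'
#' @param error An `error_signal` (or a named 3-vector, treated as all
#'   valid).
#' @param state A `controller_state`.
#' @param gains A `controller_gains`.
#' @return List with `correction_nm` (named 3-vector) and the updated
#'   `state`.
#' @export
controller_update <- function(error, state, gains) {
  if (inherits(error, "error_signal")) {
    e <- error$e_nm; valid <- error$valid
  } else {
    e <- error[AXES]; valid <- !is.na(e)
  }
  correction <- c(x = 0, y = 0, z = 0)
  for (ax in AXES) {
    if (!isTRUE(valid[[ax]])) next
    if (!is.finite(e[[ax]])) {
      stop("non-finite error on valid axis ", ax,
           ": estimator fault, refusing to actuate")
    }
    state$integral[[ax]] <- clamp(state$integral[[ax]] + e[[ax]],
                                  gains$stage_limit_nm)
    state$double_integral[[ax]] <- clamp(
      state$double_integral[[ax]] + state$integral[[ax]],
      gains$stage_limit_nm)
    raw <- -(gains$kp * e[[ax]] +
               gains$ki * state$integral[[ax]] +
               gains$kii * state$double_integral[[ax]])
    correction[[ax]] <- clamp(raw, gains$output_limit_nm)
  }
  state$last_command_nm <- correction
  list(correction_nm = correction, state = state)
}

clamp <- function(v, limit) max(-limit, min(limit, v))
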