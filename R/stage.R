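#' Sample drift model
#'
#' Deterministic-given-seed drift trajectories added to the true sample
#' position, one increment per loop iteration. Components:
#' `linear` (constant rate), `random_walk` (i.i.d. Gaussian increments),
#' `sinusoidal` (e.g. periodic laboratory-temperature coupling),
#' `composite` (sum of components), `none`.
#'
#' Random-walk increments are generated from a counter-based seed
#' (`seed`, iteration), so a trajectory is reproducible regardless of how
#' much randomness other parts of a simulation consume.
#'
#' @param kind Drift kind.
#' @param rate_nm_per_iter Per-axis linear rate, nm/iteration (length 3).
#' @param sigma_nm Per-axis random-walk increment sd, nm.
#' @param amplitude_nm,period_iters Per-axis sinusoid amplitude and
#'   common period.
#' @param components List of `drift_model`s for `kind = "composite"`.
#' @param seed Seed for stochastic components.
#' @return List of class `drift_model`.
#' @export
drift_model <- function(kind = c("none", "linear", "random_walk",
                                 "sinusoidal", "composite"),
                        rate_nm_per_iter = c(0, 0, 0),
                        sigma_nm = c(0, 0, 0),
                        amplitude_nm = c(0, 0, 0),
                        period_iters = 1000,
                        components = list(),
                        seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind,
                 rate_nm_per_iter = rep_len(rate_nm_per_iter, 3L),
                 sigma_nm = rep_len(sigma_nm, 3L),
                 amplitude_nm = rep_len(amplitude_nm, 3L),
                 period_iters = period_iters,
                 components = components,
                 seed = as.integer(seed)),
            class = "drift_model")
}

#' Drift increment at a given iteration
#' @param drift A `drift_model`.
#' @param iter Iteration counter (1-based).
#' @return Per-axis increment `c(x, y, z)` nm.
#' @export
drift_increment <- function(drift, iter) {
  switch(drift$kind,
         none = c(0, 0, 0),
         linear = drift$rate_nm_per_iter,
         random_walk = with_seed(drift$seed * 1000003 + iter,
                                 stats::rnorm(3) * drift$sigma_nm),
         sinusoidal = {
           ph <- 2 * pi / drift$period_iters
           drift$amplitude_nm * (sin(ph * iter) - sin(ph * (iter - 1)))
         },
         composite = {
           inc <- c(0, 0, 0)
           for (cmp in drift$components) inc <- inc + drift_increment(cmp, iter)
           inc
         })
}

#' Virtual piezo stage state
#'
#' The mechanical stage position relaxes toward the commanded position
#' with a first-order settle model (`settle_alpha` is the fraction of the
#' remaining distance closed per iteration; 1 = instant). Sample drift
#' accumulates independently of the stage, so the true sample position is
#' `actual_nm + drift_cum_nm`.
#'
#' @param position_nm Initial commanded/actual position.
#' @param settle_alpha Settle fraction per iteration, in (0, 1].
#' @param travel_limit_nm Absolute travel bound per axis.
#' @return List of class `stage_state`.
#' @export
stage_state <- function(position_nm = c(0, 0, 0), settle_alpha = 1,
                        travel_limit_nm = 50000) {
  stopifnot(settle_alpha > 0, settle_alpha <= 1, travel_limit_nm > 0)
  p <- stats::setNames(as.numeric(rep_len(position_nm, 3L)), AXES)
  structure(list(commanded_nm = p, actual_nm = p,
                 drift_cum_nm = stats::setNames(c(0, 0, 0), AXES),
                 iter = 0L,
                 settle_alpha = settle_alpha,
                 travel_limit_nm = travel_limit_nm,
                 clamped = FALSE),
            class = "stage_state")
}

#' Advance the stage one iteration
#'
#' Applies a (clamped) command, relaxes the mechanical position toward
#' it, and adds one drift increment to the accumulated sample drift.
#'
#' @param state A `stage_state`.
#' @param command_nm Commanded position `c(x, y, z)` nm.
#' @param drift A `drift_model`.
#' @return Updated `stage_state`; `clamped` is `TRUE` if the command hit
#'   the travel bound.
#' @export
stage_step <- function(state, command_nm = state$commanded_nm,
                       drift = drift_model("none")) {
  cmd <- as.numeric(rep_len(command_nm, 3L))
  lim <- state$travel_limit_nm
  clamped <- any(abs(cmd) > lim)
  if (clamped) {
    warning("stage command clamped to travel limit of ", lim, " nm")
    cmd <- pmin(pmax(cmd, -lim), lim)
  }
  state$clamped <- clamped
  state$commanded_nm[] <- cmd
  state$actual_nm <- state$actual_nm +
    state$settle_alpha * (state$commanded_nm - state$actual_nm)
  state$iter <- state$iter + 1L
  state$drift_cum_nm <- state$drift_cum_nm + drift_increment(drift, state$iter)
  state
}

#' True sample position of a virtual stage
#' @param state A `stage_state`.
#' @return Named 3-vector, nm: mechanical position plus accumulated drift.
#' @export
true_position <- function(state) state$actual_nm + state$drift_cum_nm
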