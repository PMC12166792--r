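#' Stabilization run configuration
#'
#' Bundles the per-axis stack settings, controller gains, calibration
#' factors and loop bookkeeping. All lengths are nm; the loop is
#' iteration-clocked with a nominal period of `period_ms` (used to
#' convert the stack settle buffer into settle iterations and for time
#' axes in analysis).
#'
#' @param stack_x,stack_y,stack_z Per-axis [axis_stack_config()]s.
#' @param gains A [controller_gains()].
#' @param calibration Named per-axis scale factors mapping raw estimator
#'   output to nm (typically 0.85--1.1 on hardware; 1 on the simulator).
#' @param period_ms Loop iteration period in ms (~16 Hz default).
#' @param max_consecutive_failures Abort the loop after this many
#'   consecutive iterations with no valid axis.
#' @param seed Seed for the run (simulator noise stream).
#' @return List of class `stab_config`.
#' @export
stab_config <- function(stack_x = axis_stack_config("x"),
                        stack_y = axis_stack_config("y"),
                        stack_z = axis_stack_config("z"),
                        gains = controller_gains(),
                        calibration = c(x = 1, y = 1, z = 1),
                        period_ms = 62.5,
                        max_consecutive_failures = 25L,
                        seed = 1L) {
  stopifnot(inherits(stack_x, "axis_stack_config"),
            inherits(stack_y, "axis_stack_config"),
            inherits(stack_z, "axis_stack_config"),
            inherits(gains, "controller_gains"),
            period_ms > 0, max_consecutive_failures >= 1)
  calibration <- calibration[AXES]
  if (anyNA(calibration) || any(calibration <= 0)) {
    stop("calibration must be positive per-axis factors named x, y, z")
  }
  structure(list(stacks = list(x = stack_x, y = stack_y, z = stack_z),
                 gains = gains, calibration = calibration,
                 period_ms = period_ms,
                 max_consecutive_failures = as.integer(max_consecutive_failures),
                 seed = as.integer(seed)),
            class = "stab_config")
}

#' Create a virtual microscope session
#'
#' Couples a scene, a noise model, a drift model and a virtual stage into
#' one simulation session, and seeds the ambient RNG so that every
#' subsequent draw (camera noise) is reproducible. The same seed and
#' configuration therefore reproduce a run bit-identically.
#'
#' @param scene A [virtual_scene()].
#' @param noise A [noise_model()] or `NULL` for noiseless imaging.
#' @param drift A [drift_model()].
#' @param stage A [stage_state()].
#' @param seed Integer seed for the session RNG stream.
#' @return List of class `sim_session`.
#' @export
sim_session <- function(scene, noise = NULL, drift = drift_model("none"),
                        stage = stage_state(), seed = 1L) {
  set.seed(as.integer(seed))
  structure(list(scene = scene, noise = noise, drift = drift,
                 stage = stage, seed = as.integer(seed),
                 exposures = 0L),
            class = "sim_session")
}

# acquire one frame at the current true sample position
session_frame <- function(session) {
  session$exposures <- session$exposures + 1L
  f <- image_at(session$scene, true_position(session$stage),
                noise = session$noise, exposure_id = session$exposures)
  list(session = session, frame = f)
}

settle_iters <- function(cfg_axis, period_ms) {
  as.integer(ceiling(cfg_axis$settle_buffer_ms / period_ms))
}

#' Acquire a reference stack on the virtual microscope
#'
#' Steps the stage over the configured symmetric range, waits for the
#' settle buffer after each move, and appends the normalized frame (x/y)
#' or its sorted intensity profile (z) to the stack. The stage is left at
#' the last plane; [engage()] is responsible for returning to start.
#'
#' @param session A `sim_session`.
#' @param cfg An [axis_stack_config()].
#' @param period_ms Loop period used to convert the settle buffer to
#'   settle iterations.
#' @return List with the updated `session` and the `stack`.
#' @export
acquire_reference_stack_sim <- function(session, cfg, period_ms = 62.5) {
  positions <- stack_positions(cfg)
  if (max(abs(positions)) > session$stage$travel_limit_nm) {
    stop("stack range exceeds stage travel")
  }
  start <- session$stage$commanded_nm
  ax_i <- match(cfg$axis, AXES)
  n_settle <- settle_iters(cfg, period_ms)
  entries <- vector("list", length(positions))
  for (k in seq_along(positions)) {
    target <- start
    target[ax_i] <- target[ax_i] + positions[k]
    session$stage <- stage_step(session$stage, target, session$drift)
    for (s in seq_len(n_settle)) {
      session$stage <- stage_step(session$stage, target, session$drift)
    }
    sf <- session_frame(session); session <- sf$session
    nf <- normalize_frame(sf$frame)
    entries[[k]] <- if (cfg$axis == "z") sorted_profile(nf) else nf
  }
  list(session = session,
       stack = reference_stack(cfg$axis, entries, positions))
}

#' Engage the stabilization on a virtual microscope
#'
#' The engagement sequence: capture the setpoint frame at the current
#' position, acquire one reference stack per axis (x, y, z), move the
#' stage back to the starting position, measure the setpoint frame's
#' offsets against the fresh stacks, and zero the controller integrators.
#' If any axis fails (setpoint beyond stack range, fit failure) nothing
#' is engaged.
#'
#' @param session A `sim_session`.
#' @param config A [stab_config()].
#' @return List of class `engaged_loop`: updated `session`, `stacks`,
#'   `setpoint`, zeroed controller `state`, `start_command_nm` and the
#'   `config`.
#' @export
engage <- function(session, config) {
  start <- session$stage$commanded_nm
  sf <- session_frame(session); session <- sf$session
  setpoint_frame <- normalize_frame(sf$frame)
  stacks <- list()
  for (ax in AXES) {
    res <- acquire_reference_stack_sim(session, config$stacks[[ax]],
                                       config$period_ms)
    session <- res$session
    stacks[[ax]] <- res$stack
    # return to start before the next axis
    session$stage <- stage_step(session$stage, start, session$drift)
    for (s in seq_len(settle_iters(config$stacks[[ax]], config$period_ms))) {
      session$stage <- stage_step(session$stage, start, session$drift)
    }
  }
  setpoint <- measure_setpoint_offsets(setpoint_frame, stacks)
  structure(list(session = session, stacks = stacks, setpoint = setpoint,
                 state = controller_state(), start_command_nm = start,
                 config = config),
            class = "engaged_loop")
}

#' Run the closed stabilization loop
#'
#' Per iteration: advance the stage (drift, settle, optional injected
#' disturbance), acquire a frame, estimate the 3D error signal against
#' the reference stacks and setpoint, update the controller and apply the
#' correction to the commanded stage position. Records one row per
#' iteration, including the simulator's ground-truth sample position.
#'
#' @param engaged An `engaged_loop` from [engage()].
#' @param n_iterations Number of loop iterations.
#' @param disturbance `NULL`, or a function `(iteration) -> c(x, y, z)`
#'   offset in nm injected into the stage command (used by the staircase
#'   protocol).
#' @return List of class `loop_run`: updated `engaged` and `records`, a
#'   data frame with columns `iter`, `t_s`, `e_*` (error signal, nm),
#'   `valid_*`, `cmd_*` (commanded stage, nm), `true_*` (ground-truth
#'   sample position, nm), `dist_*` (injected disturbance, nm) and
#'   `fitrms_*` (per-axis fit residual rms).
#' @export
run_closed_loop <- function(engaged, n_iterations, disturbance = NULL) {
  stopifnot(inherits(engaged, "engaged_loop"), n_iterations >= 1)
  session <- engaged$session
  config <- engaged$config
  state <- engaged$state
  command <- engaged$start_command_nm
  n <- as.integer(n_iterations)
  rec <- matrix(NA_real_, n, 20L)
  colnames(rec) <- c("iter", "t_s",
                     paste0("e_", AXES), paste0("valid_", AXES),
                     paste0("cmd_", AXES), paste0("true_", AXES),
                     paste0("dist_", AXES), paste0("fitrms_", AXES))
  consecutive_failures <- 0L
  for (k in seq_len(n)) {
    dist <- if (is.null(disturbance)) c(0, 0, 0) else
      as.numeric(rep_len(disturbance(k), 3L))
    session$stage <- stage_step(session$stage, command + dist, session$drift)
    sf <- session_frame(session); session <- sf$session
    err <- estimate_error(sf$frame, engaged$stacks, engaged$setpoint,
                          config$calibration)
    upd <- controller_update(err, state, config$gains)
    state <- upd$state
    command <- pmin(pmax(command + upd$correction_nm,
                         -config$gains$stage_limit_nm),
                    config$gains$stage_limit_nm)
    if (!any(err$valid)) {
      consecutive_failures <- consecutive_failures + 1L
      if (consecutive_failures > config$max_consecutive_failures) {
        stop("displacement estimation failed on every axis for ",
             consecutive_failures, " consecutive iterations (last at ",
             "iteration ", k, "): aborting loop")
      }
    } else {
      consecutive_failures <- 0L
    }
    fitrms <- vapply(AXES, function(ax) {
      f <- err$fits[[ax]]
      if (is.null(f) || !isTRUE(f$converged)) NA_real_ else f$residual_rms
    }, numeric(1))
    rec[k, ] <- c(k, k * config$period_ms / 1000,
                  err$e_nm, as.numeric(err$valid),
                  command, true_position(session$stage), dist, fitrms)
  }
  records <- as.data.frame(rec)
  for (ax in AXES) {
    records[[paste0("valid_", ax)]] <- records[[paste0("valid_", ax)]] > 0
  }
  engaged$session <- session
  engaged$state <- state
  structure(list(engaged = engaged, records = records),
            class = "loop_run")
}

#' Staircase / step-response protocol
#'
#' Steps the stage back and forth by `step_nm` around the setpoint:
#' after one baseline period the injected offset cycles through
#' `+step_nm, 0, -step_nm, 0`, changing every `period_iters` iterations.
#' Every transition is a step of `step_nm`, sampled symmetrically on both
#' sides of the setpoint, and each cycle contributes two error-increasing
#' and two error-decreasing steps, so `n_cycles` cycles give
#' `2 * n_cycles` steps in each direction. With feedback gains at zero
#' this produces the plateaus used for staircase calibration; with
#' feedback on it produces the step-response transients.
#'
#' @param engaged An `engaged_loop`.
#' @param axis Axis to step.
#' @param step_nm Step amplitude, nm (20 nm is the conventional
#'   calibration amplitude).
#' @param period_iters Iterations between transitions.
#' @param n_cycles Full back-and-forth cycles; the default 5 gives 10
#'   steps in each direction.
#' @return A `loop_run` whose `records` carry an attribute
#'   `disturbance_events`: data frame with `iter` (first iteration at the
#'   new level) and `direction` (+1 if the error signal jumps up, -1 if
#'   down).
#' @export
staircase_protocol <- function(engaged, axis = "x", step_nm = 20,
                               period_iters = 25, n_cycles = 5) {
  ax_i <- match(axis, AXES)
  half_range <- engaged$config$stacks[[axis]]$range_nm / 2
  if (step_nm > half_range) {
    warning("staircase step of ", step_nm, " nm exceeds half the ", axis,
            "-stack range (", half_range, " nm): estimates may rail")
  }
  cycle <- c(step_nm, 0, -step_nm, 0)
  n_segments <- 4L * n_cycles + 1L      # baseline + cycles
  level <- function(k) {
    seg <- (k - 1) %/% period_iters     # 0-based segment index
    if (seg == 0) 0 else cycle[(seg - 1) %% 4 + 1]
  }
  dist_fun <- function(k) {
    d <- c(0, 0, 0); d[ax_i] <- level(k); d
  }
  run <- run_closed_loop(engaged, n_segments * period_iters,
                         disturbance = dist_fun)
  ev_iter <- seq(period_iters + 1L, by = period_iters,
                 length.out = 4L * n_cycles)
  # error jump at each transition: 0->+s up, +s->0 down, 0->-s down,
  # -s->0 up
  events <- data.frame(iter = ev_iter,
                       direction = rep(c(1, -1, -1, 1), n_cycles))
  attr(run$records, "disturbance_events") <- events
  attr(run$records, "staircase") <- list(axis = axis, step_nm = step_nm,
                                         period_iters = period_iters,
                                         n_cycles = n_cycles)
  run
}
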