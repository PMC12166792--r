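AXES <- c("x", "y", "z")

estimate_axis_nm <- function(x, stack) {
  curve <- build_match_curve(x, stack)
  fit <- fit_gaussian_peak(curve)
  disp <- if (isTRUE(fit$converged)) index_to_nm(fit, stack) else NA_real_
  list(disp_nm = disp, fit = fit)
}

#' Measure the setpoint frame against freshly acquired reference stacks
#'
#' The error signal of the loop is referenced to the setpoint frame -- the
#' frame captured at engagement, *before* the stacks -- rather than to the
#' stack centers. Any drift during stack acquisition (or a systematic bias
#' of the estimator) would otherwise hold the sample at a constant offset
#' from where the user engaged. This measures that per-axis offset once.
#'
#' @param setpoint Normalized setpoint frame.
#' @param stacks Named list of `reference_stack`s for `x`, `y`, `z`.
#' @return List of class `setpoint_reference`: `setpoint_frame`,
#'   `setpoint_profile`, `offsets_nm` (named 3-vector).
#' @export
measure_setpoint_offsets <- function(setpoint, stacks) {
  stopifnot(all(AXES %in% names(stacks)))
  if (!is_normalized(setpoint)) stop("setpoint frame must be normalized")
  offsets <- vapply(AXES, function(ax) {
    res <- tryCatch(estimate_axis_nm(setpoint, stacks[[ax]]),
                    error = function(e) {
                      stop("setpoint measurement failed on axis ", ax, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (!isTRUE(res$fit$converged)) {
      stop("setpoint measurement failed on axis ", ax,
           ": peak fit did not converge; stabilization cannot engage")
    }
    half_range <- diff(range(stacks[[ax]]$positions_nm)) / 2
    if (abs(res$disp_nm) >= half_range) {
      stop("setpoint offset ", format(res$disp_nm),
           " nm on axis ", ax, " exceeds half the stack range")
    }
    res$disp_nm
  }, numeric(1))
  structure(list(setpoint_frame = setpoint,
                 setpoint_profile = sorted_profile(setpoint),
                 offsets_nm = offsets),
            class = "setpoint_reference")
}

#' Estimate the 3D error signal for one camera frame
#'
#' Runs the per-axis estimators (cross-correlation curves for x/y, sorted
#' profile MSE for z), converts fitted peak positions to nm, subtracts the
#' setpoint offsets and applies the per-axis calibration factors. An axis
#' whose peak is out of stack range or whose fit fails is flagged invalid
#' (`valid = FALSE`, `e_nm = NA`), never silently zeroed: the controller
#' must freeze that axis rather than act on garbage.
#'
#' @param x Camera frame (raw; it is normalized internally).
#' @param stacks Named list of per-axis `reference_stack`s.
#' @param setpoint A `setpoint_reference` from [measure_setpoint_offsets()].
#' @param calibration Named per-axis scale factors (dimensionless);
#'   hardware calibrations typically land between 0.85 and 1.1.
#' @return List of class `error_signal`: `e_nm` (named 3-vector, nm),
#'   `valid` (named logical 3-vector), `fits` (per-axis `gaussian_fit`).
#' @export
estimate_error <- function(x, stacks, setpoint,
                           calibration = c(x = 1, y = 1, z = 1)) {
  stopifnot(inherits(setpoint, "setpoint_reference"))
  calibration <- calibration[AXES]
  xn <- if (is_normalized(x)) x else normalize_frame(x)
  e <- structure(rep(NA_real_, 3), names = AXES)
  valid <- structure(rep(FALSE, 3), names = AXES)
  fits <- stats::setNames(vector("list", 3), AXES)
  for (ax in AXES) {
    res <- tryCatch(estimate_axis_nm(xn, stacks[[ax]]),
                    error = function(err) NULL)
    if (is.null(res)) next
    fits[[ax]] <- res$fit
    if (isTRUE(res$fit$converged)) {
      e[[ax]] <- calibration[[ax]] *
        (res$disp_nm - setpoint$offsets_nm[[ax]])
      valid[[ax]] <- TRUE
    }
  }
  structure(list(e_nm = e, valid = valid, fits = fits),
            class = "error_signal")
}
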