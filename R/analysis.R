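#' Stability statistics of a loop log
#'
#' The headline figure of merit is the per-axis standard deviation of the
#' error signal ("in-loop stability"), computed over valid samples only.
#' Rolling mean and rolling standard deviation over a centered window
#' summarize slow residuals; at the edges the window shrinks to the
#' available samples (so the rolling series has one entry per log row).
#'
#' @param records Loop record data frame (from [run_closed_loop()] or
#'   [read_loop_log()]), columns `e_x/e_y/e_z` and `valid_*`.
#' @param window Rolling window length in samples (default 1000).
#' @return List of class `stability_stats`: `sigma_nm` (named 3-vector),
#'   `rolling` (list per axis of data frames `mean`/`sd`), `n_samples`,
#'   `window`.
#' @export
stability_stats <- function(records, window = 1000) {
  if (is.null(records) || nrow(records) == 0L) stop("empty loop log")
  stopifnot(window >= 2)
  sigma <- vapply(AXES, function(ax) {
    e <- records[[paste0("e_", ax)]][records[[paste0("valid_", ax)]]]
    if (length(e) < 2L) NA_real_ else stats::sd(e)
  }, numeric(1))
  rolling <- lapply(AXES, function(ax) {
    e <- records[[paste0("e_", ax)]]
    e[!records[[paste0("valid_", ax)]]] <- NA
    rolling_mean_sd(e, window)
  })
  names(rolling) <- AXES
  structure(list(sigma_nm = sigma, rolling = rolling,
                 n_samples = nrow(records), window = as.integer(window)),
            class = "stability_stats")
}

# centered rolling mean/sd with shrink-at-edges; for even windows the
# window covers [i - w/2, i + w/2 - 1]; NAs (invalid samples) excluded
rolling_mean_sd <- function(e, window) {
  n <- length(e)
  lo_off <- floor(window / 2)
  hi_off <- ceiling(window / 2) - 1
  ok <- !is.na(e)
  x <- ifelse(ok, e, 0)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  cn <- cumsum(c(0, as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(1L, i - lo_off)
  hi <- pmin(n, i + hi_off)
  cnt <- cn[hi + 1] - cn[lo]
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  m <- ifelse(cnt > 0, s / cnt, NA_real_)
  v <- ifelse(cnt > 1, pmax(0, (s2 - cnt * m^2) / (cnt - 1)), NA_real_)
  data.frame(mean = m, sd = sqrt(v))
}

#' Fit the averaged step response
#'
#' Aligns the error-signal segments following each injected disturbance,
#' folds negative-direction steps by sign flip, averages them, and fits a
#' delayed exponential decay: the response is modeled as holding the step
#' amplitude `alpha` until a dead time `t0` and decaying as
#' `alpha * exp(-(t - t0)/tau)` afterwards. Times are in iterations
#' unless `period_s` is given.
#'
#' @param records Staircase loop records (feedback on).
#' @param events Data frame `iter`/`direction` of disturbance events;
#'   defaults to the `disturbance_events` attribute of `records`.
#' @param axis Axis to analyze.
#' @param period_s Optional loop period in seconds to express `t0`/`tau`
#'   in seconds.
#' @return List of class `step_response_fit`: `alpha` (nm), `t0`, `tau`,
#'   `residual_rms`, `n_steps_averaged`, `response` (the averaged folded
#'   response) and `time_unit`.
#' @export
fit_step_response <- function(records, events = NULL, axis = "x",
                              period_s = NULL) {
  if (is.null(events)) events <- attr(records, "disturbance_events")
  if (is.null(events) || nrow(events) < 1L) {
    stop("no disturbance events supplied")
  }
  e <- records[[paste0("e_", axis)]]
  n <- nrow(records)
  gaps <- diff(c(events$iter, n + 1L))
  L <- min(gaps)
  if (L < 5L) stop("segments between disturbances too short to fit")
  segs <- vapply(seq_len(nrow(events)), function(j) {
    idx <- events$iter[j] + 0:(L - 1L)
    events$direction[j] * e[idx]
  }, numeric(L))
  avg <- rowMeans(segs, na.rm = TRUE)
  if (all(!is.finite(avg)) || max(abs(avg), na.rm = TRUE) < 1e-12 ||
      stats::sd(avg, na.rm = TRUE) < 1e-12) {
    stop("averaged step response is flat: no disturbance effect to fit")
  }
  tt <- 0:(L - 1L)
  p <- fit_delayed_exponential(tt, avg, L)
  if (is.null(p)) stop("step-response fit failed to converge")
  if (p[["tau"]] > 10 * L) {
    stop("averaged step response does not decay within the segment: ",
         "fitted decay constant ", signif(p[["tau"]], 3),
         " iterations exceeds the observable window")
  }
  pred <- p[["alpha"]] * exp(-pmax(tt - p[["t0"]], 0) / p[["tau"]])
  scale_t <- if (is.null(period_s)) 1 else period_s
  structure(list(alpha = p[["alpha"]],
                 t0 = p[["t0"]] * scale_t,
                 tau = p[["tau"]] * scale_t,
                 residual_rms = sqrt(mean((avg - pred)^2)),
                 n_steps_averaged = nrow(events),
                 response = avg,
                 time_unit = if (is.null(period_s)) "iterations" else "s"),
            class = "step_response_fit")
}

# Least squares for alpha * exp(-max(t - t0, 0)/tau): alpha is linear
# given (t0, tau), so profile it over a (t0, tau) grid, then polish the
# best grid point with Levenberg-Marquardt. The dead-time kink makes a
# single gradient descent unreliable.
fit_delayed_exponential <- function(tt, y, L) {
  shape <- function(t0, tau) exp(-pmax(tt - t0, 0) / tau)
  ssr_of <- function(t0, tau) {
    g <- shape(t0, tau)
    a <- sum(y * g) / sum(g * g)
    if (!is.finite(a) || a <= 0) return(list(ssr = Inf, alpha = NA))
    list(ssr = sum((y - a * g)^2), alpha = a)
  }
  best <- list(ssr = Inf)
  for (t0 in seq(0, min(L / 2, 12), by = 0.25)) {
    for (tau in exp(seq(log(0.3), log(2 * L), length.out = 40))) {
      cand <- ssr_of(t0, tau)
      if (cand$ssr < best$ssr) {
        best <- list(ssr = cand$ssr, alpha = cand$alpha, t0 = t0, tau = tau)
      }
    }
  }
  if (!is.finite(best$ssr)) return(NULL)
  polish <- tryCatch(
    minpack.lm::nls.lm(
      par = c(alpha = best$alpha, t0 = best$t0, tau = best$tau),
      fn = function(p) y - p[1] * exp(-pmax(tt - p[2], 0) / p[3]),
      lower = c(1e-12, 0, 1e-6), upper = c(Inf, L / 2, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(polish)) {
    pp <- polish$par
    g <- shape(pp[[2]], pp[[3]])
    if (sum((y - pp[[1]] * g)^2) <= best$ssr + 1e-12) {
      return(c(alpha = pp[[1]], t0 = pp[[2]], tau = pp[[3]]))
    }
  }
  c(alpha = best$alpha, t0 = best$t0, tau = best$tau)
}

#' Staircase calibration of the error signal
#'
#' With feedback off, stepping the stage back and forth by a known
#' amount produces plateaus in the error signal. Each plateau level is
#' estimated robustly (median of the linearly detrended segment,
#' evaluated at the segment midpoint, so slow drift during the
#' calibration does not bias it); the per-transition amplitudes give the
#' scale factor `commanded / measured` with a t-based confidence
#' interval.
#'
#' @param records Staircase loop records acquired with all gains zero.
#' @param events Disturbance events (default: attribute of `records`).
#' @param axis Stepped axis.
#' @param commanded_step_nm Commanded staircase amplitude (default 20 nm).
#' @param conf Confidence level for the interval.
#' @param settle_skip Iterations to drop at the start of each plateau.
#' @return List of class `calibration_result`: `scale`, `ci` (2-vector),
#'   `amplitude_nm` (measured), `n_transitions`.
#' @export
calibrate <- function(records, events = NULL, axis = "x",
                      commanded_step_nm = 20, conf = 0.95,
                      settle_skip = 2L) {
  if (commanded_step_nm == 0) stop("staircase amplitude must be nonzero")
  if (is.null(events)) events <- attr(records, "disturbance_events")
  if (is.null(events) || nrow(events) < 3L) {
    stop("need at least 4 plateaus (3 transitions) to calibrate")
  }
  e <- records[[paste0("e_", axis)]]
  n <- nrow(records)
  bounds <- c(1L, events$iter, n + 1L)
  levels <- vapply(seq_len(length(bounds) - 1L), function(j) {
    idx <- (bounds[j] + settle_skip):(bounds[j + 1L] - 1L)
    idx <- idx[idx >= 1 & idx <= n]
    y <- e[idx]
    t <- seq_along(y)
    keep <- is.finite(y)
    if (sum(keep) < 3L) return(NA_real_)
    co <- stats::coef(stats::lm(y[keep] ~ t[keep]))
    stats::median(y[keep] - co[2] * (t[keep] - mean(t[keep])))
  }, numeric(1))
  amp <- abs(diff(levels))
  amp <- amp[is.finite(amp)]
  if (length(amp) < 3L) stop("too few usable plateau transitions")
  noise <- mean(vapply(seq_len(length(bounds) - 1L), function(j) {
    idx <- (bounds[j] + settle_skip):(bounds[j + 1L] - 1L)
    idx <- idx[idx >= 1 & idx <= n]
    y <- e[idx]
    if (sum(is.finite(y)) < 3L) return(NA_real_)
    stats::sd(y, na.rm = TRUE)
  }, numeric(1)), na.rm = TRUE)
  if (!is.finite(mean(amp)) || mean(amp) < 2 * noise / sqrt(2)) {
    stop("staircase plateaus indistinguishable from noise: ",
         "mean amplitude ", signif(mean(amp), 3), " nm vs plateau sd ",
         signif(noise, 3), " nm")
  }
  scales <- abs(commanded_step_nm) / amp
  m <- mean(scales)
  se <- stats::sd(scales) / sqrt(length(scales))
  q <- stats::qt(1 - (1 - conf) / 2, df = length(scales) - 1L)
  structure(list(scale = m, ci = c(m - q * se, m + q * se),
                 amplitude_nm = mean(amp), n_transitions = length(amp),
                 conf = conf),
            class = "calibration_result")
}

#' Drift-reduction factors from paired position tracks
#'
#' Compares a stabilized and an unstabilized track of equal length:
#' per-axis root-mean-square displacement after mean centering, and
#' reduction factors `rms_off / rms_on`. A perfectly still stabilized
#' track would give an infinite factor; it is reported as a lower bound
#' (`lower_bound = TRUE`, factor `NA`) instead.
#'
#' @param track_on,track_off Data frames with columns `x_nm`, `y_nm`,
#'   `z_nm` (stabilization on / off), equal row counts.
#' @return List of class `track_stats`: `rms_on_nm`, `rms_off_nm`,
#'   `factors`, `lower_bound` (per-axis logical).
#' @export
drift_reduction <- function(track_on, track_off) {
  cols <- paste0(AXES, "_nm")
  stopifnot(all(cols %in% names(track_on)), all(cols %in% names(track_off)))
  if (nrow(track_on) != nrow(track_off)) {
    stop("tracks must have equal duration/sampling (",
         nrow(track_on), " vs ", nrow(track_off), " samples)")
  }
  rms <- function(v) sqrt(mean((v - mean(v))^2))
  rms_on <- vapply(cols, function(cl) rms(track_on[[cl]]), numeric(1))
  rms_off <- vapply(cols, function(cl) rms(track_off[[cl]]), numeric(1))
  names(rms_on) <- names(rms_off) <- AXES
  lower <- rms_on == 0
  factors <- ifelse(lower, NA_real_, rms_off / rms_on)
  structure(list(rms_on_nm = rms_on, rms_off_nm = rms_off,
                 factors = factors, lower_bound = lower),
            class = "track_stats")
}
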