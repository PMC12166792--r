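#' Match a frame against a reference stack
#'
#' For a lateral (x/y) stack the raw curve is the cross-correlation of the
#' normalized frame with every stack entry; the best-matching plane gives
#' the largest CC. For the z stack the frame is reduced to its sorted
#' intensity profile and the raw curve is the MSE against every stored
#' profile; the best plane gives the smallest MSE, so the curve is
#' inverted (multiplied by -1) before scaling. In both cases the curve is
#' then min-max scaled to [0, 1] so a single peak-fitting routine serves
#' all axes.
#'
#' @param x Normalized frame.
#' @param stack A `reference_stack`.
#' @return List of class `match_curve` with fields `axis`, `metric`
#'   (`"cc"` or `"mse"`), `raw` and `scaled`.
#' @export
build_match_curve <- function(x, stack) {
  if (!is_normalized(x)) stop("frame must be normalized before matching")
  if (stack$axis == "z") {
    prof <- sorted_profile(x)
    n <- length(stack$entries[[1L]])
    if (length(prof) != n) {
      stop("profile length ", length(prof),
           " does not match stack profile length ", n)
    }
    raw <- vapply(stack$entries, function(e) profile_mse(prof, e), numeric(1))
    scaled <- minmax_scale(-raw)
    metric <- "mse"
  } else {
    d0 <- dim(unclass_frame(stack$entries[[1L]]))
    if (!identical(dim(unclass_frame(x)), d0)) {
      stop("frame shape does not match stack entry shape")
    }
    raw <- vapply(stack$entries, function(e) cross_correlation(x, e),
                  numeric(1))
    scaled <- minmax_scale(raw)
    metric <- "cc"
  }
  structure(list(axis = stack$axis, metric = metric, raw = raw,
                 scaled = scaled),
            class = "match_curve")
}

minmax_scale <- function(v) {
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) {
    stop("flat match curve: min equals max, scaling undefined")
  }
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Fit a Gaussian peak to a scaled match curve
#'
#' Fits `A * exp(-(u - mu)^2 / (2 w^2)) + c` to the (plane index, scaled
#' value) pairs by nonlinear least squares (Levenberg-Marquardt). The
#' four-parameter form (with baseline `c`) is used because scaled curves
#' generally sit on a nonzero baseline. The fit uses a window of
#' `window_halfwidth` planes around the argmax (lowest index on ties),
#' clipped at the curve ends: far-tail points carry no information about
#' the peak position, but on asymmetric curves they pull the
#' least-squares center towards the curve interior -- with the peak one
#' plane from the stack edge the full-curve fit is biased by up to a
#' quarter plane, the windowed fit by a few hundredths.
#'
#' The argmax must be interior: a peak at either end means the sample has
#' drifted to (or beyond) the edge of the reference stack range, where the
#' peak position cannot be interpolated, and an error is raised.
#'
#' @param curve A `match_curve` (or a bare numeric vector of scaled
#'   values).
#' @param window_halfwidth Planes on each side of the argmax included in
#'   the fit (default 3, i.e. up to 7 points).
#' @return List of class `gaussian_fit`: `center_index` (fractional,
#'   1-based), `amplitude`, `width`, `offset`, `converged`, `residual_rms`.
#'   On non-convergence `converged` is `FALSE` and the caller must skip
#'   actuation for this axis.
#' @export
fit_gaussian_peak <- function(curve, window_halfwidth = 3L) {
  y_all <- if (inherits(curve, "match_curve")) curve$scaled
           else as.numeric(curve)
  n <- length(y_all)
  if (n < 5L) stop("need at least 5 curve points to fit a peak")
  imax <- which.max(y_all)       # which.max takes the lowest index on ties
  if (imax == 1L || imax == n) {
    stop("match-curve peak at plane ", imax,
         " is on the stack boundary: displacement out of stack range")
  }
  lo <- max(1L, imax - window_halfwidth)
  hi <- min(n, imax + window_halfwidth)
  u <- lo:hi
  y <- y_all[u]
  # w is capped at the curve length: an unbounded width is degenerate
  # with the baseline on shallow (near-parabolic) curves, sending A, w to
  # infinity while the center stays put. Width is multi-started (narrow
  # and broad) because a single start can settle into a spike or plateau
  # local minimum; the lowest-SSR solution wins.
  fit <- NULL
  for (w_start in c(1, n / 4)) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = c(A = max(y) - min(y), mu = as.numeric(imax), w = w_start,
                c = min(y)),
        fn = function(p) y - (p[1] * exp(-(u - p[2])^2 / (2 * p[3]^2)) +
                                p[4]),
        lower = c(1e-12, lo, 1e-6, -Inf),
        upper = c(Inf, hi, n, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 5000,
                                             ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    ok <- !is.null(cand) && cand$info %in% c(1:4, 6:8) &&
      all(is.finite(cand$par))
    if (ok && (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    return(structure(list(center_index = NA_real_, amplitude = NA_real_,
                          width = NA_real_, offset = NA_real_,
                          converged = FALSE, residual_rms = NA_real_),
                     class = "gaussian_fit"))
  }
  p <- fit$par
  structure(list(center_index = p[[2]],
                 amplitude = p[[1]],
                 width = p[[3]],
                 offset = p[[4]],
                 converged = TRUE,
                 residual_rms = sqrt(mean(fit$fvec^2))),
            class = "gaussian_fit")
}

#' Convert a fitted peak index to a displacement in nanometers
#'
#' The fractional center index of the Gaussian, measured against the
#' stack's center plane, times the plane spacing. Positive values mean
#' the sample is displaced toward increasing stage coordinate.
#'
#' @param fit A converged `gaussian_fit`.
#' @param stack The `reference_stack` the curve was built against.
#' @return Displacement in nm.
#' @export
index_to_nm <- function(fit, stack) {
  if (!isTRUE(fit$converged)) stop("cannot convert a non-converged fit")
  (fit$center_index - stack$center_index) * stack$step_nm
}
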