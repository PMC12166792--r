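#' Per-axis reference stack acquisition settings
#'
#' The stack covers `range_nm` symmetrically about the stage starting
#' position with planes every `step_nm`, so the plane count is
#' `range_nm / step_nm + 1`. The count must be odd (and at least 3) so a
#' center plane exists at zero relative position. Defaults follow a
#' typical configuration: 20 nm steps and 11 planes per axis, i.e. a
#' 200 nm span.
#'
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param range_nm Total span in nm, symmetric about the start position.
#' @param step_nm Plane spacing in nm, > 0.
#' @param settle_buffer_ms Extra wait after each stage move, in ms. The
#'   virtual stage converts this into settle iterations; on hardware it
#'   would be a real delay.
#' @return List of class `axis_stack_config`.
#' @export
axis_stack_config <- function(axis = c("x", "y", "z"), range_nm = 200,
                              step_nm = 20, settle_buffer_ms = 100) {
  axis <- match.arg(axis)
  stopifnot(step_nm > 0, range_nm > 0)
  n <- range_nm / step_nm + 1
  if (abs(n - round(n)) > 1e-9) {
    stop("range_nm / step_nm must be an integer plane count")
  }
  n <- as.integer(round(n))
  if (n < 3L) stop("stack needs at least 3 planes")
  if (n %% 2L == 0L) stop("plane count must be odd so a center plane exists")
  structure(list(axis = axis, range_nm = range_nm, step_nm = step_nm,
                 n_planes = n, settle_buffer_ms = settle_buffer_ms),
            class = "axis_stack_config")
}

#' Stack plane positions relative to the start position
#' @param cfg An `axis_stack_config`.
#' @return Numeric vector of relative stage positions in nm, centered on 0.
#' @export
stack_positions <- function(cfg) {
  seq(-cfg$range_nm / 2, cfg$range_nm / 2, by = cfg$step_nm)
}

#' Assemble a reference stack
#'
#' @param axis Axis label.
#' @param entries List of normalized frames (x/y) or sorted profiles (z),
#'   one per plane.
#' @param positions_nm Stage position of each entry relative to the stack
#'   center; strictly increasing, uniformly spaced, with a zero entry.
#' @return List of class `reference_stack` with fields `axis`, `entries`,
#'   `positions_nm`, `step_nm`, `center_index` (1-based).
#' @export
reference_stack <- function(axis, entries, positions_nm) {
  stopifnot(length(entries) == length(positions_nm), length(entries) >= 3L)
  d <- diff(positions_nm)
  if (any(d <= 0)) stop("positions_nm must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d)) {
    stop("positions_nm must be uniformly spaced")
  }
  center_index <- which(abs(positions_nm) < 1e-9)
  if (length(center_index) != 1L) {
    stop("positions_nm must contain exactly one zero (the center plane)")
  }
  if (axis == "z") {
    ok <- vapply(entries, function(e) inherits(e, "sorted_profile"), logical(1))
    if (!all(ok)) stop("z stack entries must be sorted profiles")
  } else {
    ok <- vapply(entries, is_normalized, logical(1))
    if (!all(ok)) stop("lateral stack entries must be normalized frames")
  }
  structure(list(axis = axis, entries = entries,
                 positions_nm = as.numeric(positions_nm),
                 step_nm = mean(d), center_index = center_index),
            class = "reference_stack")
}

#' @export
print.reference_stack <- function(x, ...) {
  kind <- if (x$axis == "z") "sorted profiles" else "frames"
  cat(sprintf("<reference_stack %s: %d %s, step %.3g nm, span %.3g nm>\n",
              x$axis, length(x$entries), kind, x$step_nm,
              diff(range(x$positions_nm))))
  invisible(x)
}
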