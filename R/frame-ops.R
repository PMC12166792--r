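#' Construct a camera frame
#'
#' A frame is a numeric matrix of non-negative pixel intensities with a
#' monotone exposure counter. Row/column indexing is 1-based, row-major in
#' the usual R sense, with the origin at the top-left of the sensor ROI.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities, at
#'   least 8 x 8.
#' @param exposure_id Integer exposure counter.
#' @param normalized Logical; `TRUE` if the pixel values sum to one.
#' @return A numeric matrix of class `stab_frame` with attributes
#'   `exposure_id` and `normalized`.
#' @export
frame <- function(pixels, exposure_id = 0L, normalized = FALSE) {
  pixels <- check_pixels(pixels)
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("frame must be at least 8 x 8 pixels, got ",
         nrow(pixels), " x ", ncol(pixels))
  }
  if (normalized) {
    s <- sum(pixels)
    if (abs(s - 1) > 1e-9 * max(1, abs(s))) {
      stop("frame flagged normalized but pixel sum is ", format(s))
    }
  }
  structure(pixels,
            exposure_id = as.integer(exposure_id),
            normalized = isTRUE(normalized),
            class = c("stab_frame", class(pixels)))
}

check_pixels <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixel intensities must all be finite")
  }
  if (any(pixels < 0)) stop("pixel intensities must be non-negative")
  pixels
}

#' Normalize a frame to unit total intensity
#'
#' Divides every pixel by the sum over all pixels, so that frames acquired
#' at different illumination or exposure levels become comparable. This is
#' applied to every frame before it enters a reference stack or a
#' displacement estimate; without it, slow gain or illumination changes
#' masquerade as displacements.
#'
#' @param x Numeric matrix or `stab_frame`.
#' @return Matrix of the same shape summing to 1. Attributes
#'   (`exposure_id`) are preserved; `normalized` is set to `TRUE`.
#' @export
#' @examples
#' normalize_frame(matrix(c(2, 0, 0, 2), 2))
normalize_frame <- function(x) {
  p <- check_pixels(unclass_frame(x))
  s <- sum(p)
  if (s <= 0) stop("cannot normalize an all-zero frame")
  out <- p / s
  attributes(out) <- attributes(x)[names(attributes(x)) != "dim"]
  dim(out) <- dim(p)
  attr(out, "normalized") <- TRUE
  out
}

unclass_frame <- function(x) {
  if (inherits(x, "stab_frame")) {
    a <- attributes(x)
    attributes(x) <- list(dim = a$dim)
  }
  x
}

is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Unshifted cross-correlation of two images
#'
#' `CC(a, b) = sum_ij a_ij * b_ij`: the plain elementwise product sum, with
#' no shift search. Shifts are explored by comparing against reference
#' stack entries recorded at known stage positions rather than by sliding
#' one image over the other.
#'
#' @param a,b Numeric matrices of identical shape.
#' @return Scalar cross-correlation value.
#' @export
cross_correlation <- function(a, b) {
  a <- unclass_frame(a); b <- unclass_frame(b)
  if (!is.matrix(a) || !is.matrix(b)) stop("inputs must be matrices")
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  sum(a * b)
}

#' Sorted intensity profile of a frame
#'
#' Flattens the frame to a 1D vector and sorts the pixel intensities in
#' non-decreasing order. The profile discards all spatial information but
#' its shape varies smoothly with defocus, which is what makes axial
#' position readable from it.
#'
#' @param x Normalized frame (matrix).
#' @return Numeric vector of length `nrow * ncol`, non-decreasing, of class
#'   `sorted_profile`.
#' @export
sorted_profile <- function(x) {
  p <- unclass_frame(x)
  if (!is_normalized(x)) {
    stop("frame must be normalized before computing its sorted profile")
  }
  structure(sort(as.vector(p), method = "radix"),
            class = "sorted_profile")
}

#' Mean squared error between two sorted profiles
#'
#' `MSE(a, b) = mean((a_i - b_i)^2)` over equal-length 1D arrays.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Scalar MSE, non-negative, zero iff the arrays are identical.
#' @export
profile_mse <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  mean((a - b)^2)
}
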