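#' Camera noise model
#'
#' Shot noise (Poisson) plus Gaussian read noise and a constant offset,
#' clipped to the sensor range. The scene's brightest pixel is mapped to
#' `frac_saturation * sensor_max` expected counts; illumination tuned so
#' the brightest pixel sits at 60--80% of saturation is a good operating
#' point, so the default is 0.7. Counts are treated as photoelectrons
#' (unit gain).
#'
#' @param frac_saturation Fraction of `sensor_max` for the brightest
#'   scene pixel.
#' @param sensor_max Saturation level in counts (16-bit: 65535).
#' @param read_sigma Read noise standard deviation, counts.
#' @param offset Constant camera offset, counts.
#' @return List of class `noise_model`.
#' @export
noise_model <- function(frac_saturation = 0.7, sensor_max = 65535,
                        read_sigma = 10, offset = 100) {
  stopifnot(frac_saturation > 0, frac_saturation <= 1, sensor_max > 0,
            read_sigma >= 0, offset >= 0)
  structure(list(frac_saturation = frac_saturation,
                 sensor_max = sensor_max,
                 read_sigma = read_sigma, offset = offset),
            class = "noise_model")
}

#' Image the scene at a given sample position
#'
#' Forward model of the stabilization camera: the scene is evaluated on a
#' supersampled grid displaced by the lateral sample position (an exact,
#' analytic sub-pixel shift -- no interpolation kernel), area-binned to
#' camera pixels, blurred with an isotropic Gaussian defocus kernel of
#' width `w(z) = w0 * sqrt(1 + (zeff/zR)^2)` where
#' `zeff = z + defocus_nm`, and finally passed through the noise model.
#' The kernel width grows monotonically with |zeff|, which broadens the
#' frame's intensity histogram away from focus -- the mechanism the axial
#' estimator reads out. Note `w(z)` is even in `zeff`: exactly in focus
#' the axial readout is sign-blind, which is why the operating point has
#' nonzero defocus.
#'
#' The margin needed by the blur kernel is rendered and discarded, so
#' structures flow in and out of the ROI correctly under displacement.
#'
#' @param scene A `virtual_scene`.
#' @param position_nm Sample position `c(x, y, z)` nm relative to the
#'   scene origin / engage focus.
#' @param noise A `noise_model`, or `NULL` for the noiseless expectation.
#'   Noise consumes the ambient R random number stream.
#' @param exposure_id Exposure counter stored on the frame.
#' @return A `stab_frame` of size `field_px` in camera counts.
#' @export
image_at <- function(scene, position_nm = c(0, 0, 0), noise = NULL,
                     exposure_id = 0L) {
  position_nm <- as.numeric(rep_len(position_nm, 3L))
  if (any(abs(position_nm[1:2]) > scene$max_shift_nm)) {
    stop("lateral position ", paste(round(position_nm[1:2], 1),
                                    collapse = "/"),
         " nm outside simulated range (", scene$max_shift_nm, " nm)")
  }
  zeff <- position_nm[3] + scene$defocus_nm
  w_nm <- scene$psf_w0_nm * sqrt(1 + (zeff / scene$psf_zr_nm)^2)
  sigma_px <- w_nm / scene$pixel_size_nm   # c(x, y)
  margin <- ceiling(3.5 * max(sigma_px)) + 1L
  ss <- scene$supersample
  nr <- scene$field_px[1]; nc <- scene$field_px[2]
  xs <- ss_coords(nc, ss, scene$pixel_size_nm[1], margin) + position_nm[1]
  ys <- ss_coords(nr, ss, scene$pixel_size_nm[2], margin) + position_nm[2]
  hi <- scene_value(scene, xs, ys)
  img <- bin_ss(hi, ss)
  img <- gauss_blur(img, sigma_row = sigma_px[2], sigma_col = sigma_px[1])
  img <- img[(margin + 1):(margin + nr), (margin + 1):(margin + nc),
             drop = FALSE]
  peak <- scene$background + scene$base_intensity
  if (is.null(noise)) {
    counts <- img / peak * 65535 * 0.7
  } else {
    gain <- noise$frac_saturation * noise$sensor_max / peak
    counts <- stats::rpois(length(img), lambda = as.vector(img) * gain)
    counts <- counts + noise$offset +
      stats::rnorm(length(counts), sd = noise$read_sigma)
    counts <- matrix(pmin(pmax(counts, 0), noise$sensor_max),
                     nrow(img), ncol(img))
  }
  frame(counts, exposure_id = exposure_id)
}

# average ss x ss blocks of a supersampled matrix
bin_ss <- function(m, ss) {
  if (ss == 1L) return(m)
  nr <- nrow(m) %/% ss; nc <- ncol(m) %/% ss
  dim(m) <- c(ss, nr, ss * nc)
  m <- colMeans(m)                 # nr x (ss*nc)
  m <- t(m)                        # (ss*nc) x nr
  dim(m) <- c(ss, nc, nr)
  t(colMeans(m))                   # nr x nc
}

# separable Gaussian blur via banded convolution matrices; edge rows are
# renormalized but callers keep a margin >= 3.5 sigma so the retained
# region sees a complete kernel
gauss_blur <- function(m, sigma_row, sigma_col) {
  if (sigma_row > 1e-6) m <- gauss_band(nrow(m), sigma_row) %*% m
  if (sigma_col > 1e-6) m <- m %*% t(gauss_band(ncol(m), sigma_col))
  m
}

gauss_band <- function(n, sigma) {
  r <- ceiling(3.5 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    keep <- idx + o >= 1 & idx + o <= n
    K[cbind(idx[keep], idx[keep] + o)] <- k[o + r + 1]
  }
  K / rowSums(K)
}

# evaluate an expression with a temporary, derived RNG seed, restoring the
# ambient RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
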