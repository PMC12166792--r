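#' Define a virtual sample scene
#'
#' Parametric ground-truth reflectivity patterns mimicking structures
#' commonly used for image-based stabilization: a holey carbon support
#' film (dark circular holes on a bright film, square lattice), a sparse
#' field of scattering beads, and a magnification calibration target with
#' a square tile grid. Geometry parameters are in micrometers (the
#' natural unit for these structures); everything is converted to
#' nanometers internally and all positions/displacements elsewhere in the
#' package are nm.
#'
#' Pattern edges are rendered with a smooth logistic profile
#' (`edge_width_um`) so that sub-pixel displacements change pixel values
#' continuously; hard binary edges would quantize sub-pixel shifts at the
#' supersampling resolution.
#'
#' @param pattern `"holey_carbon"`, `"bead_field"` or `"tile_target"`.
#' @param field_px Camera ROI size, `c(rows, cols)` pixels.
#' @param pixel_size_nm Camera pixel size `c(x, y)` nm in the sample
#'   plane; mildly anisotropic sensors are supported (e.g. 75/78 nm).
#' @param supersample Integer supersampling factor (>= 4) for rendering
#'   relative to camera pixels.
#' @param base_intensity,background Reflectivity scale of the structure
#'   and additive background, arbitrary units; the noise model maps the
#'   brightest scene value to a target camera count.
#' @param hole_diameter_um,hole_spacing_um Holey-carbon geometry: hole
#'   diameter and edge-to-edge spacing (centers sit on a square lattice
#'   of pitch diameter + spacing). Defaults 2 and 2.
#' @param hole_contrast Reflectivity inside a hole relative to the film.
#' @param edge_width_um Logistic edge width of pattern features.
#' @param n_beads,bead_sigma_nm Bead field: count and Gaussian spot sigma.
#' @param bead_positions Optional `n x 2` matrix of bead centers (nm,
#'   relative to field center); drawn uniformly from `seed` if `NULL`.
#' @param tile_pitch_um,line_width_um Tile target: tile pitch (default 10)
#'   and grid line width.
#' @param defocus_nm Operating defocus of the stabilization path at stage
#'   z = 0. Axial readout needs the intensity histogram to change with z,
#'   which vanishes exactly in focus; a moderate defocus of ~2 um is the
#'   recommended operating point.
#' @param psf_w0_nm,psf_zr_nm Defocus blur model: kernel width
#'   `w(z) = w0 * sqrt(1 + (z/zR)^2)` (Gaussian-beam-style broadening).
#' @param max_shift_nm Largest lateral displacement the scene will image.
#' @param seed Seed for random scene content (bead positions).
#' @return List of class `virtual_scene`.
#' @export
virtual_scene <- function(pattern = c("holey_carbon", "bead_field",
                                      "tile_target"),
                          field_px = c(300L, 300L),
                          pixel_size_nm = c(75, 78),
                          supersample = 4L,
                          base_intensity = 1,
                          background = 0.1,
                          hole_diameter_um = 2,
                          hole_spacing_um = 2,
                          hole_contrast = 0.35,
                          edge_width_um = 0.1,
                          n_beads = 40L,
                          bead_sigma_nm = 150,
                          bead_positions = NULL,
                          tile_pitch_um = 10,
                          line_width_um = 0.5,
                          defocus_nm = 2000,
                          psf_w0_nm = 500,
                          psf_zr_nm = 2000,
                          max_shift_nm = 5000,
                          seed = 1L) {
  pattern <- match.arg(pattern)
  field_px <- as.integer(rep_len(field_px, 2L))
  pixel_size_nm <- rep_len(pixel_size_nm, 2L)
  supersample <- as.integer(supersample)
  stopifnot(all(field_px >= 8L), all(pixel_size_nm > 0), supersample >= 4L,
            hole_diameter_um > 0, hole_spacing_um > 0, tile_pitch_um > 0,
            bead_sigma_nm > 0, psf_w0_nm > 0, psf_zr_nm > 0,
            base_intensity > 0, background >= 0)
  ss_px_nm <- min(pixel_size_nm) / supersample
  feature_nm <- switch(pattern,
                       holey_carbon = hole_diameter_um * 1000,
                       bead_field = bead_sigma_nm,
                       tile_target = line_width_um * 1000)
  if (feature_nm < 2 * ss_px_nm) {
    stop("pattern feature (", feature_nm, " nm) smaller than 2 ",
         "supersampled pixels (", 2 * ss_px_nm, " nm): increase ",
         "supersample or feature size")
  }
  if (pattern == "bead_field" && is.null(bead_positions)) {
    half <- (field_px[2:1] * pixel_size_nm) / 2
    bead_positions <- with_seed(seed, cbind(
      stats::runif(n_beads, -half[1], half[1]),
      stats::runif(n_beads, -half[2], half[2])))
  }
  structure(list(pattern = pattern, field_px = field_px,
                 pixel_size_nm = pixel_size_nm, supersample = supersample,
                 base_intensity = base_intensity, background = background,
                 hole_pitch_nm = (hole_diameter_um + hole_spacing_um) * 1000,
                 hole_radius_nm = hole_diameter_um * 500,
                 hole_contrast = hole_contrast,
                 edge_width_nm = edge_width_um * 1000,
                 n_beads = if (is.null(bead_positions)) 0L
                           else nrow(bead_positions),
                 bead_positions = bead_positions,
                 bead_sigma_nm = bead_sigma_nm,
                 tile_pitch_nm = tile_pitch_um * 1000,
                 line_width_nm = line_width_um * 1000,
                 defocus_nm = defocus_nm,
                 psf_w0_nm = psf_w0_nm, psf_zr_nm = psf_zr_nm,
                 max_shift_nm = max_shift_nm, seed = seed),
            class = "virtual_scene")
}

# Evaluate the (unblurred) scene reflectivity at world coordinates.
# xs, ys are vectors of nm coordinates; returns a length(ys) x length(xs)
# matrix (rows = y, cols = x).
scene_value <- function(scene, xs, ys) {
  sig <- function(d) stats::plogis(d / (scene$edge_width_nm / 4))
  val <- switch(
    scene$pattern,
    holey_carbon = {
      p <- scene$hole_pitch_nm
      rx <- xs - p * round(xs / p)
      ry <- ys - p * round(ys / p)
      r <- sqrt(outer(ry^2, rx^2, `+`))
      # film = 1, holes = hole_contrast, logistic edge
      scene$hole_contrast +
        (1 - scene$hole_contrast) * sig(r - scene$hole_radius_nm)
    },
    bead_field = {
      m <- matrix(0, length(ys), length(xs))
      s2 <- 2 * scene$bead_sigma_nm^2
      if (scene$n_beads > 0L) {
        for (b in seq_len(scene$n_beads)) {
          gx <- exp(-(xs - scene$bead_positions[b, 1])^2 / s2)
          gy <- exp(-(ys - scene$bead_positions[b, 2])^2 / s2)
          m <- m + outer(gy, gx)
        }
      }
      pmin(m, 1)
    },
    tile_target = {
      p <- scene$tile_pitch_nm
      hw <- scene$line_width_nm / 2
      dx <- abs(xs - p * round(xs / p))
      dy <- abs(ys - p * round(ys / p))
      # dark grid lines on bright tiles
      lx <- 1 - sig(hw - dx)
      ly <- 1 - sig(hw - dy)
      1 - 0.8 * (1 - outer(ly, lx))
    })
  scene$background + scene$base_intensity * val
}

#' Render the ground-truth scene map
#'
#' Evaluates the scene reflectivity on the supersampled grid covering the
#' camera field, with the sample at the origin and no defocus blur or
#' noise: the ideal pattern the camera would see with a perfect lens.
#' Mostly useful for inspecting scene geometry; the camera model is
#' [image_at()].
#'
#' @param scene A `virtual_scene`.
#' @return Numeric matrix of size `field_px * supersample`.
#' @export
render_scene <- function(scene) {
  ss <- scene$supersample
  xs <- ss_coords(scene$field_px[2], ss, scene$pixel_size_nm[1], 0L)
  ys <- ss_coords(scene$field_px[1], ss, scene$pixel_size_nm[2], 0L)
  scene_value(scene, xs, ys)
}

# supersampled sample-plane coordinates for n camera pixels with a margin
# of `margin` camera pixels on each side, centered on the field
ss_coords <- function(n, ss, px_nm, margin) {
  idx <- seq((0.5 - margin * ss) / ss, n + margin - 0.5 / ss, by = 1 / ss)
  (idx - n / 2) * px_nm
}
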