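#' Detector geometry
#'
#' Describes the square pixel detector used by the speckle simulator: pixel
#' grid, physical pixel size, sample-detector distance and beam center. The
#' scattering-vector map uses the flat-Ewald (small-angle) approximation
#' `q = (2*pi/lambda) * (pixel offset / distance)`, so a real-valued
#' scatterer gives exactly centrosymmetric (Friedel) intensities.
#'
#' The default pixel size and distance are chosen so that a toy particle of
#' ~100 Angstrom diameter produces speckle fringes with a period of roughly
#' 3-10 pixels; they are a desk-scale stand-in, not an instrument model.
#'
#' @param n_rows,n_cols Pixel counts (default 172 x 172).
#' @param pixel_size Pixel edge length in meters.
#' @param detector_distance Sample-detector distance in meters.
#' @param beam_center Fractional pixel coordinates `(row, col)` of the beam
#'   axis, 1-based with pixel centers at integers. Default: detector center.
#' @return An object of class `speckle_geometry`.
#' @export
detector_geometry <- function(n_rows = 172L, n_cols = 172L,
                              pixel_size = 2e-4, detector_distance = 0.02,
                              beam_center = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("detector must have positive dimensions")
  assert_positive(pixel_size, "pixel_size")
  assert_positive(detector_distance, "detector_distance")
  if (is.null(beam_center)) beam_center <- c((n_rows + 1) / 2, (n_cols + 1) / 2)
  if (length(beam_center) != 2L || any(!is.finite(beam_center)) ||
      beam_center[1] < 0.5 || beam_center[1] > n_rows + 0.5 ||
      beam_center[2] < 0.5 || beam_center[2] > n_cols + 0.5) {
    stop("beam_center must lie on the detector")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size,
                 detector_distance = detector_distance,
                 beam_center = as.numeric(beam_center)),
            class = "speckle_geometry")
}

#' X-ray beam profile
#'
#' @param photon_energy Photon energy in keV (default 1.66).
#' @param photons_per_pulse Photons per pulse (default 1e12).
#' @param beam_radius Focal spot radius in micrometers (default 0.5).
#' @return An object of class `speckle_beam`; the wavelength in Angstrom is
#'   derived as `12.39842 / photon_energy`.
#' @export
beam_profile <- function(photon_energy = 1.66, photons_per_pulse = 1e12,
                         beam_radius = 0.5) {
  assert_positive(photon_energy, "photon_energy")
  assert_positive(photons_per_pulse, "photons_per_pulse")
  assert_positive(beam_radius, "beam_radius")
  structure(list(photon_energy = photon_energy,
                 photons_per_pulse = photons_per_pulse,
                 beam_radius = beam_radius,
                 wavelength = 12.39842 / photon_energy),
            class = "speckle_beam")
}

# Transverse scattering-vector map in 1/Angstrom (flat Ewald): two
# n_rows x n_cols matrices, exactly antisymmetric about the beam center.
q_map <- function(geometry, beam) {
  g <- geometry
  rows <- (seq_len(g$n_rows) - g$beam_center[1]) * g$pixel_size
  cols <- (seq_len(g$n_cols) - g$beam_center[2]) * g$pixel_size
  k <- 2 * pi / beam$wavelength / g$detector_distance
  list(qr = matrix(rows * k, g$n_rows, g$n_cols),
       qc = matrix(cols * k, g$n_rows, g$n_cols, byrow = TRUE))
}

#' Detector mask set
#'
#' Builds the binary masks applied to simulated patterns: a `6 x 8` pixel
#' beam stop centered on the beam center (rounded to the nearest pixel), a
#' 4-column gap across the middle of the detector, and an optional extra
#' mask. Masked pixels are `TRUE`.
#'
#' @param geometry A [detector_geometry()].
#' @param beam_stop Beam-stop block size `(rows, cols)`; `NULL` for none.
#' @param gap_width Width in columns of the central panel gap; `NULL` for none.
#' @param extra Optional additional logical mask of detector shape.
#' @return An object of class `speckle_masks` with elements `beam_stop`,
#'   `gap`, `extra` and their union `combined`.
#' @export
mask_set <- function(geometry, beam_stop = c(6L, 8L), gap_width = 4L,
                     extra = NULL) {
  g <- geometry
  empty <- matrix(FALSE, g$n_rows, g$n_cols)
  bs <- empty
  if (!is.null(beam_stop)) {
    ctr <- round(g$beam_center)
    r0 <- ctr[1] - beam_stop[1] %/% 2L
    c0 <- ctr[2] - beam_stop[2] %/% 2L
    rr <- pmax(1L, r0 + 1L):pmin(g$n_rows, r0 + beam_stop[1])
    cc <- pmax(1L, c0 + 1L):pmin(g$n_cols, c0 + beam_stop[2])
    bs[rr, cc] <- TRUE
  }
  gap <- empty
  if (!is.null(gap_width) && gap_width > 0L) {
    c0 <- (g$n_cols - as.integer(gap_width)) %/% 2L
    gap[, (c0 + 1L):(c0 + as.integer(gap_width))] <- TRUE
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (!all(dim(extra) == c(g$n_rows, g$n_cols))) {
      stop("extra mask shape does not match the detector")
    }
    extra <- extra > 0
  } else {
    extra <- empty
  }
  structure(list(beam_stop = bs, gap = gap, extra = extra,
                 combined = bs | gap | extra),
            class = "speckle_masks")
}

#' Mask out detector pixels
#'
#' Sets every pixel under the combined mask to `fill`, leaving all other
#' pixels untouched.
#'
#' @param image Numeric matrix.
#' @param masks A [mask_set()] or a logical matrix of the same shape.
#' @param fill Replacement value for masked pixels (default 0).
#' @return The masked image.
#' @export
apply_masks <- function(image, masks, fill = 0) {
  m <- if (inherits(masks, "speckle_masks")) masks$combined else masks > 0
  if (!all(dim(m) == dim(image))) stop("mask shape does not match the image")
  image[m] <- fill
  image
}

#' Crop the central window of an image
#'
#' The crop window starts at row/column `floor((n - size)/2) + 1`, a fixed
#' convention so results are bit-reproducible for even and odd sizes.
#'
#' @param image Numeric matrix.
#' @param size Edge length of the square crop (default 96).
#' @return A `size x size` matrix.
#' @export
center_crop <- function(image, size = 96L) {
  size <- as.integer(size)
  d <- dim(image)
  if (size > d[1] || size > d[2]) {
    stop("crop size ", size, " exceeds image dimensions ", d[1], "x", d[2])
  }
  r0 <- (d[1] - size) %/% 2L
  c0 <- (d[2] - size) %/% 2L
  image[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size), drop = FALSE]
}
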