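# Forward model: far-field coherent diffraction in the flat-Ewald
# (small-angle) approximation with unit point-atom form factors,
#   I(q) = s * | sum_copies sum_atoms w * exp(i q . (R r + t)) |^2 .
# Copies are summed coherently, so multi-hits show interference fringes.

# Default overall intensity scale, relative to photons_per_pulse: calibrated
# once so that a default 100-atom toy particle single-hit integrates to
# roughly 1e5 photons on the default detector, keeping Poisson noise in a
# realistic regime. Configurable through the `scale` argument.
INTENSITY_SCALE_PER_PHOTON <- 3e-14

#' Noise-free diffraction intensity
#'
#' Computes the coherent far-field intensity of one or more particle copies
#' on the detector. Each element of `placements` is a list with elements
#' `particle` (a [particle()]), `rotation` (unit quaternion `(w, x, y, z)`,
#' identity if omitted) and `displacement` (length-3 vector in Angstrom,
#' zero if omitted).
#'
#' @param placements List of particle placements (>= 1).
#' @param geometry A [detector_geometry()].
#' @param beam A [beam_profile()].
#' @param scale Overall intensity scale; default
#'   `photons_per_pulse * 3e-14` (see package vignette).
#' @return Matrix of non-negative expected photon counts.
#' @export
diffraction_intensity <- function(placements, geometry, beam, scale = NULL) {
  if (!is.list(placements) || length(placements) == 0L) {
    stop("placements must be a non-empty list of particle placements")
  }
  if (inherits(placements, "speckle_particle")) {
    placements <- list(list(particle = placements))
  }
  scale <- scale %||% (beam$photons_per_pulse * INTENSITY_SCALE_PER_PHOTON)
  q <- q_map(geometry, beam)
  qr <- as.vector(q$qr)
  qc <- as.vector(q$qc)
  amp <- complex(real = numeric(length(qr)), imaginary = numeric(length(qr)))
  for (pl in placements) {
    p <- pl$particle
    if (!inherits(p, "speckle_particle")) stop("each placement needs a particle")
    R <- quat_to_matrix(pl$rotation %||% c(1, 0, 0, 0))
    t3 <- pl$displacement %||% c(0, 0, 0)
    xyz <- p$coords %*% t(R)
    xyz <- sweep(xyz, 2L, t3, `+`)
    # flat Ewald: only the transverse coordinates enter the phase
    phase <- outer(qr, xyz[, 1]) + outer(qc, xyz[, 2])
    amp <- amp + exp(1i * phase) %*% p$weights
  }
  matrix(scale * Re(amp * Conj(amp)), geometry$n_rows, geometry$n_cols)
}

#' Non-sample-hit proxy pattern
#'
#' Generates a smooth low-spatial-frequency image standing in for parasitic
#' scattering (the dominant source of non-sample hits): the sum of one to
#' three broad anisotropic Gaussian streaks with random orientation,
#' scaled to a given total intensity. This is a functional proxy chosen to
#' be statistically distinguishable from particle speckle, not a physical
#' model.
#'
#' @param geometry A [detector_geometry()].
#' @param beam A [beam_profile()].
#' @param seed Integer seed; the image is deterministic per seed.
#' @param total_photons Total expected intensity of the pattern.
#' @return Matrix of non-negative intensities.
#' @export
simulate_non_sample_hit <- function(geometry, beam, seed = 1L,
                                    total_photons = 1e5) {
  g <- geometry
  with_seed(seed, {
    img <- matrix(0, g$n_rows, g$n_cols)
    rows <- seq_len(g$n_rows) - g$beam_center[1]
    cols <- seq_len(g$n_cols) - g$beam_center[2]
    X <- matrix(rows, g$n_rows, g$n_cols)
    Y <- matrix(cols, g$n_rows, g$n_cols, byrow = TRUE)
    n_streaks <- sample.int(3L, 1L)
    for (k in seq_len(n_streaks)) {
      theta <- stats::runif(1, 0, pi)
      s_long <- stats::runif(1, 30, 80)
      s_short <- stats::runif(1, 5, 15)
      off <- stats::rnorm(2, 0, 6)
      u <- (X - off[1]) * cos(theta) + (Y - off[2]) * sin(theta)
      v <- -(X - off[1]) * sin(theta) + (Y - off[2]) * cos(theta)
      img <- img + stats::runif(1, 0.5, 1) *
        exp(-0.5 * (u / s_long)^2 - 0.5 * (v / s_short)^2)
    }
    img * (total_photons / sum(img))
  })
}
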