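# Detector noise chain: fluence jitter -> Poisson shot noise; additive
# Gaussian read-out noise is applied on the intensity-normalized scale
# (a relative sigma of 0.15 only makes sense on an O(1) scale).

#' Poisson shot noise
#'
#' Replaces each pixel by an independent Poisson draw with the pixel value
#' as its mean.
#'
#' @param image Non-negative matrix of expected counts.
#' @param seed Integer seed.
#' @return Integer-valued matrix of observed photon counts.
#' @export
apply_shot_noise <- function(image, seed = 1L) {
  if (any(image < 0)) stop("shot noise requires non-negative intensities")
  with_seed(seed, {
    counts <- stats::rpois(length(image), as.vector(image))
    matrix(as.numeric(counts), nrow(image), ncol(image))
  })
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. `N(0, sigma^2)` noise per pixel. Intended for the
#' intensity-normalized scale, where the default `sigma = 0.15` emulates
#' detector read-out noise.
#'
#' @param image Numeric matrix.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Noisy image.
#' @export
apply_gaussian_noise <- function(image, sigma = 0.15, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  with_seed(seed, image + matrix(stats::rnorm(length(image), 0, sigma),
                                 nrow(image), ncol(image)))
}

#' Log-normal fluence-multiplier sampler
#'
#' Shot-to-shot photon fluence jitter is emulated by a log-normal
#' multiplier with median 1 and a long right tail, standing in for an
#' experimental pulse-energy histogram; an empirical sample vector can be
#' used instead via [fluence_sampler_empirical()].
#'
#' @param meanlog,sdlog Log-normal parameters (median `exp(meanlog)`).
#' @return A function `f(n)` drawing `n` multipliers.
#' @export
fluence_sampler_lognormal <- function(meanlog = 0, sdlog = 0.6) {
  force(meanlog); force(sdlog)
  function(n) stats::rlnorm(n, meanlog, sdlog)
}

#' Empirical fluence-multiplier sampler
#'
#' @param samples Positive numeric vector of observed multipliers, resampled
#'   with replacement.
#' @return A function `f(n)` drawing `n` multipliers.
#' @export
fluence_sampler_empirical <- function(samples) {
  assert_positive(samples, "fluence samples")
  function(n) sample(samples, n, replace = TRUE)
}

#' Fluence jitter
#'
#' Rescales a pattern by a random positive multiplier drawn from the given
#' sampler; non-positive draws are rejected and redrawn.
#'
#' @param image Numeric matrix.
#' @param sampler A function `f(n)` returning multipliers, e.g.
#'   [fluence_sampler_lognormal()].
#' @param seed Integer seed.
#' @return List with elements `image` (rescaled) and `multiplier`.
#' @export
apply_fluence_jitter <- function(image, sampler = fluence_sampler_lognormal(),
                                 seed = 1L) {
  m <- with_seed(seed, {
    mult <- sampler(1L)
    tries <- 0L
    while (mult <= 0 && tries < 100L) {
      mult <- sampler(1L)
      tries <- tries + 1L
    }
    if (mult <= 0) stop("fluence sampler kept returning non-positive values")
    mult
  })
  list(image = image * m, multiplier = m)
}

#' Per-image intensity normalization
#'
#' Standardizes an image to zero mean and unit variance (over unmasked
#' pixels when a mask is given), removing the overall intensity scale:
#' `normalize_intensity(c * x)` equals `normalize_intensity(x)` for any
#' `c > 0`. A constant image maps to all zeros.
#'
#' @param image Numeric matrix.
#' @param mask Optional logical matrix of pixels to exclude from the
#'   mean/sd estimate (they are still transformed).
#' @return Normalized image.
#' @export
normalize_intensity <- function(image, mask = NULL) {
  v <- if (is.null(mask)) image else image[!mask]
  mu <- mean(v)
  sd_ <- stats::sd(as.vector(v))
  if (!is.finite(sd_) || sd_ == 0) {
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - mu) / sd_
}
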