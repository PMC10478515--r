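# Labeled speckle-pattern datasets. A dataset is a tibble with one row per
# pattern: `image` (list of matrices), `label`, `sample_id`, `copies`,
# `fluence`, `seed`, `source_id`, `is_augmented`, `partition`. All
# generation is a pure function of the configuration and a master seed.

#' Hit-class labels
#'
#' The three pulse outcomes the simulator generates and the classifiers
#' distinguish: exactly one particle in the beam, two or more particles,
#' or a non-sample object (parasitic scattering).
#' @export
hit_classes <- c("single_hit", "multi_hit", "non_sample_hit")

# One noise-free pattern (before fluence jitter): coherent sum over particle
# copies for hit classes, Gaussian-streak proxy for non-sample hits.
simulate_clean_image <- function(class, particle, geometry, beam,
                                 multi_copy_probs, displacement_scale,
                                 non_sample_total, seed) {
  if (class == "non_sample_hit") {
    return(list(image = simulate_non_sample_hit(geometry, beam, seed,
                                                non_sample_total),
                copies = NA_integer_))
  }
  with_seed(seed, {
    copies <- if (class == "single_hit") 1L else {
      sample(2:4, 1L, prob = multi_copy_probs)
    }
    placements <- lapply(seq_len(copies), function(i) {
      disp <- if (i == 1L) c(0, 0, 0) else {
        v <- stats::rnorm(3)
        v / sqrt(sum(v * v)) * displacement_scale * stats::runif(1)^(1 / 3)
      }
      list(particle = particle, rotation = random_quaternion(),
           displacement = disp)
    })
    list(image = diffraction_intensity(placements, geometry, beam),
         copies = copies)
  })
}

# factor scales intensity before shot noise (used by the fluence scan).
finish_image <- function(raw, masks, crop_size, seed, factor = 1) {
  img <- apply_shot_noise(raw * factor, seed = seed)
  if (!is.null(masks)) img <- apply_masks(img, masks)
  center_crop(img, crop_size)
}

#' Simulate a labeled speckle-pattern dataset
#'
#' Generates a balanced dataset of the three hit classes. Single hits place
#' one randomly oriented particle copy in the beam; multi-hits place 2-4
#' copies (double/triple/quadruple pooled under one `multi_hit` label) that
#' scatter coherently, so their patterns carry interference fringes;
#' non-sample hits use the parasitic-scattering proxy. Each noise-free
#' pattern is rescaled by a fluence-jitter multiplier, Poisson sampled,
#' masked, and center cropped.
#'
#' @param n_per_class Patterns per class (>= 1).
#' @param classes Subset of `r paste(hit_classes, collapse = ", ")`.
#' @param particles List of [particle()] objects (the "samples"); patterns
#'   cycle over them so every sample contributes equally per class. Default:
#'   four 100-atom toy particles of 50 Angstrom radius.
#' @param geometry,beam,masks Simulation setup; `masks = NULL` disables
#'   masking.
#' @param crop_size Center-crop window (default 96).
#' @param multi_copy_probs Probabilities of 2, 3 and 4 copies for
#'   multi-hits.
#' @param displacement_scale Radius (Angstrom) of the ball from which
#'   copy displacements are drawn; default three times the particle extent.
#' @param fluence_sampler Multiplier sampler, see
#'   [fluence_sampler_lognormal()].
#' @param non_sample_total Total intensity of non-sample-hit patterns.
#' @param seed Master seed; the dataset is bit-reproducible given the seed.
#' @param keep_raw Keep the noise-free, unmasked, uncropped image (column
#'   `image_raw`) for protocols that rescale fluence before the noise chain.
#' @return A tibble of speckle patterns.
#' @export
simulate_dataset <- function(n_per_class,
                             classes = hit_classes,
                             particles = NULL,
                             geometry = detector_geometry(),
                             beam = beam_profile(),
                             masks = mask_set(geometry),
                             crop_size = 96L,
                             multi_copy_probs = c(1, 1, 1) / 3,
                             displacement_scale = NULL,
                             fluence_sampler = fluence_sampler_lognormal(),
                             non_sample_total = 1e5,
                             seed = 1L,
                             keep_raw = FALSE) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  unknown <- setdiff(classes, hit_classes)
  if (length(unknown) > 0L) {
    stop("unknown class name(s): ", paste(unknown, collapse = ", "))
  }
  if (length(classes) == 0L) stop("classes must be non-empty")
  if (is.null(particles)) {
    particles <- lapply(1:4, function(i) {
      random_particle(100L, 50, seed = derive_seed(seed, "toy", i),
                      particle_id = paste0("toy", i))
    })
  }
  if (inherits(particles, "speckle_particle")) particles <- list(particles)

  rows <- list()
  for (cls in classes) {
    for (i in seq_len(n_per_class)) {
      pat_seed <- derive_seed(seed, cls, i)
      part <- particles[[(i - 1L) %% length(particles) + 1L]]
      disp <- displacement_scale %||% (3 * max(sqrt(rowSums(part$coords^2))))
      clean <- simulate_clean_image(cls, part, geometry, beam,
                                    multi_copy_probs, disp,
                                    non_sample_total,
                                    derive_seed(pat_seed, "clean"))
      jit <- apply_fluence_jitter(clean$image, fluence_sampler,
                                  derive_seed(pat_seed, "jitter"))
      img <- finish_image(jit$image, masks, crop_size,
                          derive_seed(pat_seed, "shot"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image = list(img),
        image_raw = if (keep_raw) list(jit$image) else list(NULL),
        label = cls,
        sample_id = if (cls == "non_sample_hit") "background" else part$particle_id,
        copies = clean$copies,
        fluence = jit$multiplier,
        seed = pat_seed,
        source_id = paste0(cls, "_", i),
        is_augmented = FALSE,
        partition = NA_character_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!keep_raw) out$image_raw <- NULL
  out
}

#' Two-class dataset with distinct fringe spacings
#'
#' A synthetic benchmark of two well-separated classes: single-hit patterns
#' from toy particles of two different radii. Speckle fringe period scales
#' inversely with particle size, so the classes differ in a physically
#' meaningful, learnable feature rather than in arbitrary noise.
#'
#' @param n_per_class Patterns per class.
#' @param radii Named vector of two (or more) particle radii in Angstrom;
#'   names become class labels.
#' @param samples_per_class Number of distinct toy particles per class.
#' @param n_atoms Atoms per toy particle.
#' @inheritParams simulate_dataset
#' @return A tibble of speckle patterns labeled by particle-size class.
#' @export
simulate_fringe_classes <- function(n_per_class,
                                    radii = c(small = 22, large = 60),
                                    samples_per_class = 4L,
                                    n_atoms = 100L,
                                    geometry = detector_geometry(),
                                    beam = beam_profile(),
                                    masks = mask_set(geometry),
                                    crop_size = 96L,
                                    fluence_sampler = fluence_sampler_lognormal(),
                                    seed = 1L,
                                    keep_raw = FALSE) {
  stopifnot(length(radii) >= 2L, !is.null(names(radii)))
  rows <- list()
  for (cls in names(radii)) {
    parts <- lapply(seq_len(samples_per_class), function(j) {
      random_particle(n_atoms, radii[[cls]],
                      seed = derive_seed(seed, "part", cls, j),
                      particle_id = paste0(cls, "_", j))
    })
    for (i in seq_len(n_per_class)) {
      pat_seed <- derive_seed(seed, "fringe", cls, i)
      part <- parts[[(i - 1L) %% length(parts) + 1L]]
      clean <- simulate_clean_image("single_hit", part, geometry, beam,
                                    c(1, 1, 1) / 3, 0, 1e5,
                                    derive_seed(pat_seed, "clean"))
      jit <- apply_fluence_jitter(clean$image, fluence_sampler,
                                  derive_seed(pat_seed, "jitter"))
      img <- finish_image(jit$image, masks, crop_size,
                          derive_seed(pat_seed, "shot"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image = list(img),
        image_raw = list(if (keep_raw) jit$image else NULL),
        label = cls,
        sample_id = part$particle_id,
        copies = 1L,
        fluence = jit$multiplier,
        seed = pat_seed,
        source_id = paste0(cls, "_", i),
        is_augmented = FALSE,
        partition = NA_character_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!keep_raw) out$image_raw <- NULL
  out
}

#' Prepare patterns for the network
#'
#' Standardizes each image to zero mean and unit variance (removing the
#' overall fluence scale as far as possible) and adds Gaussian read-out
#' noise on that normalized scale. This is the last step before embedding
#' or classification.
#'
#' @param data Pattern tibble.
#' @param gaussian_sigma Noise standard deviation on the normalized scale
#'   (default 0.15; 0 disables).
#' @param seed Master seed for the noise draws.
#' @return The tibble with its `image` column preprocessed.
#' @export
preprocess_patterns <- function(data, gaussian_sigma = 0.15, seed = 1L) {
  data$image <- purrr::imap(data$image, function(img, i) {
    img <- normalize_intensity(img)
    apply_gaussian_noise(img, gaussian_sigma, derive_seed(seed, "gauss", i))
  })
  data
}

# Stack the image column into a (pixels x N) matrix for the network.
pattern_matrix <- function(data) {
  stopifnot(nrow(data) > 0L)
  do.call(cbind, lapply(data$image, as.vector))
}

#' Write / read a speckle dataset
#'
#' Datasets are stored as single-file R serializations holding the pattern
#' tibble plus the integer label map (0 = non_sample_hit, 1 = single_hit,
#' 2 = multi_hit) and format version.
#'
#' @param data Pattern tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_speckle_dataset <- function(data, path) {
  saveRDS(list(format = "speckfew_dataset", version = 1L,
               label_map = c(non_sample_hit = 0L, single_hit = 1L,
                             multi_hit = 2L),
               patterns = data),
          path)
  invisible(path)
}

#' @rdname write_speckle_dataset
#' @export
read_speckle_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "speckfew_dataset")) {
    stop(path, " is not a speckle dataset file")
  }
  x$patterns
}
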