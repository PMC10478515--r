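# Simulator: geometry, masks, cropping, particles, forward model, noise.

test_that("mask set matches the documented beam-stop and gap placement", {
  g <- detector_geometry()
  m <- mask_set(g)
  expect_equal(dim(m$combined), c(172L, 172L))
  expect_equal(sum(m$beam_stop), 6L * 8L)
  expect_equal(sum(m$gap), 172L * 4L)
  # union size from a brute-force pixel count over the two rectangles
  brute <- sum(m$beam_stop | m$gap)
  img <- matrix(1, 172, 172)
  masked <- apply_masks(img, m)
  expect_equal(sum(masked == 0), brute)
  expect_true(all(masked[!m$combined] == 1))
})

test_that("apply_masks handles empty and full masks and shape mismatch", {
  img <- matrix(runif(25), 5, 5)
  expect_identical(apply_masks(img, matrix(FALSE, 5, 5)), img)
  expect_equal(apply_masks(img, matrix(TRUE, 5, 5), fill = 7),
               matrix(7, 5, 5))
  expect_error(apply_masks(img, matrix(TRUE, 4, 5)), "shape")
})

test_that("center_crop follows the floor((n - size)/2) convention", {
  img4 <- matrix(1:16, 4, 4)
  expect_identical(center_crop(img4, 4L), img4)
  # start index floor((4-2)/2)+1 = 2 -> rows/cols 2:3
  expect_identical(center_crop(img4, 2L), img4[2:3, 2:3])
  big <- matrix(rnorm(172^2), 172, 172)
  expect_equal(dim(center_crop(big, 96L)), c(96L, 96L))
  expect_error(center_crop(img4, 5L), "exceeds")
})

test_that("random_particle is deterministic and fills a uniform ball", {
  p1 <- random_particle(1L, 10)
  expect_s3_class(p1, "speckle_particle")
  expect_lte(sqrt(sum(p1$coords^2)), 10)
  expect_identical(random_particle(50L, 20, seed = 9)$coords,
                   random_particle(50L, 20, seed = 9)$coords)
  expect_error(random_particle(0L, 10))
  expect_error(random_particle(10L, -1))
  # RMS radius of a uniform ball is radius * sqrt(3/5)
  p <- random_particle(1000L, 50, seed = 4)
  r <- sqrt(rowSums(p$coords^2))
  expect_true(all(r <= 50))
  rms <- sqrt(mean(r^2))
  expect_lt(abs(rms - 50 * sqrt(3 / 5)) / (50 * sqrt(3 / 5)), 0.2)
})

test_that("PDB reader returns literal coordinates and counts HETATM", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(path, n_atom = 3L)
  p <- load_pdb_coordinates(path)
  expect_equal(nrow(p$coords), 3L)
  expect_equal(p$coords[2, ], c(3.0, 5.0, -2.0))
  expect_equal(p$weights, rep(1, 3))

  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(path2, n_atom = 2L, n_hetatm = 2L)
  expect_equal(nrow(load_pdb_coordinates(path2)$coords), 4L)

  path3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), path3)
  expect_error(load_pdb_coordinates(path3), basename(path3), fixed = TRUE)
  expect_error(load_pdb_coordinates("no/such/file.pdb"), "not found")
})

test_that("single point scatterer gives a flat intensity", {
  g <- tiny_geometry()
  b <- tiny_beam()
  p <- particle(matrix(0, 1, 3))
  img <- diffraction_intensity(list(list(particle = p)), g, b, scale = 1)
  expect_equal(max(img) - min(img), 0, tolerance = 1e-12)
  expect_equal(img[1, 1], 1, tolerance = 1e-12)
})

test_that("zero-angle intensity adds coherently (k^2 law)", {
  g <- detector_geometry(n_rows = 33L, n_cols = 33L)  # integer center pixel
  b <- tiny_beam()
  p <- particle(matrix(c(0, 0, 0, 7.3, -2.1, 4.4), 2, 3, byrow = TRUE))
  img2 <- diffraction_intensity(list(list(particle = p)), g, b, scale = 1)
  ctr <- round(g$beam_center)
  expect_equal(img2[ctr[1], ctr[2]], 4, tolerance = 1e-10)
  # k identical in-phase copies at the same position: I(0) = k^2
  p1 <- particle(matrix(c(1, 2, 3), 1, 3))
  for (k in c(2L, 3L)) {
    copies <- replicate(k, list(particle = p1), simplify = FALSE)
    imgk <- diffraction_intensity(copies, g, b, scale = 1)
    expect_equal(imgk[ctr[1], ctr[2]], k^2, tolerance = 1e-10)
  }
})

test_that("vectorized forward model matches the naive per-atom sum", {
  g <- detector_geometry(n_rows = 24L, n_cols = 24L)
  b <- tiny_beam()
  p <- random_particle(50L, 30, seed = 8)
  rot <- speckfew:::with_seed(3, speckfew:::random_quaternion())
  disp <- c(5, -3, 2)
  img <- diffraction_intensity(list(list(particle = p, rotation = rot,
                                         displacement = disp)), g, b,
                               scale = 1)
  # independent oracle: explicit double loop over pixels and atoms
  R <- speckfew:::quat_to_matrix(rot)
  xyz <- sweep(p$coords %*% t(R), 2, disp, `+`)
  q <- speckfew:::q_map(g, b)
  oracle <- matrix(0, 24, 24)
  for (i in 1:24) {
    for (j in 1:24) {
      a <- 0 + 0i
      for (at in seq_len(nrow(xyz))) {
        ph <- q$qr[i, j] * xyz[at, 1] + q$qc[i, j] * xyz[at, 2]
        a <- a + exp(1i * ph)
      }
      oracle[i, j] <- Mod(a)^2
    }
  }
  expect_lt(max(abs(img - oracle)) / max(oracle), 1e-8)
})

test_that("noise-free unmasked patterns obey Friedel symmetry", {
  b <- tiny_beam()
  g <- detector_geometry(n_rows = 31L, n_cols = 31L)  # center on a pixel
  for (s in 1:3) {
    p <- random_particle(30L, 40, seed = s)
    rot <- speckfew:::with_seed(s + 10, speckfew:::random_quaternion())
    img <- diffraction_intensity(list(list(particle = p, rotation = rot)),
                                 g, b, scale = 1)
    flipped <- img[31:1, 31:1]
    expect_lt(max(abs(img - flipped)) / max(img), 1e-8)
  }
})

test_that("diffraction errors on empty input and bad quaternions", {
  g <- tiny_geometry()
  b <- tiny_beam()
  expect_error(diffraction_intensity(list(), g, b), "non-empty")
  p <- particle(matrix(0, 1, 3))
  expect_error(
    diffraction_intensity(list(list(particle = p, rotation = c(1, 1, 0, 0))),
                          g, b),
    "unit norm")
})

test_that("non-sample-hit proxy is smooth, positive and seeded", {
  g <- detector_geometry()
  b <- tiny_beam()
  i1 <- simulate_non_sample_hit(g, b, seed = 5)
  i2 <- simulate_non_sample_hit(g, b, seed = 5)
  expect_identical(i1, i2)
  expect_gt(sum(i1), 0)
  # high-frequency band power well below that of particle speckle at
  # matched total intensity
  band_power <- function(img) {
    f <- Mod(stats::fft(img))^2
    n <- nrow(img)
    fr <- pmin(0:(n - 1), n - (0:(n - 1))) / n
    hi <- outer(fr, fr, function(a, b) pmax(a, b) > 0.25)
    mean(f[hi])
  }
  bp_ns <- vapply(1:20, function(s) {
    band_power(simulate_non_sample_hit(g, b, seed = s, total_photons = 1e5))
  }, numeric(1))
  p <- random_particle(100L, 50, seed = 2)
  bp_sh <- vapply(1:20, function(s) {
    rot <- speckfew:::with_seed(s, speckfew:::random_quaternion())
    img <- diffraction_intensity(list(list(particle = p, rotation = rot)),
                                 g, b)
    band_power(img * (1e5 / sum(img)))
  }, numeric(1))
  expect_lt(mean(bp_ns), mean(bp_sh))
})

test_that("shot noise is Poisson with the right mean and reproducible", {
  expect_identical(apply_shot_noise(matrix(0, 10, 10)), matrix(0, 10, 10))
  img <- matrix(1e6, 172, 172)
  n1 <- apply_shot_noise(img, seed = 1)
  expect_identical(n1, apply_shot_noise(img, seed = 1))
  # CLT: mean over 172^2 pixels within 1% of 1e6
  expect_lt(abs(mean(n1) - 1e6) / 1e6, 0.01)
  expect_error(apply_shot_noise(matrix(-1, 2, 2)), "non-negative")
})

test_that("gaussian noise has the requested scale", {
  img <- matrix(rnorm(172^2), 172, 172)
  expect_identical(apply_gaussian_noise(img, sigma = 0), img)
  n1 <- apply_gaussian_noise(img, sigma = 0.15, seed = 2)
  expect_identical(n1, apply_gaussian_noise(img, sigma = 0.15, seed = 2))
  expect_lt(abs(sd(as.vector(n1 - img)) - 0.15) / 0.15, 0.05)
})

test_that("fluence jitter rescales and records the multiplier", {
  img <- matrix(runif(16), 4, 4)
  r1 <- apply_fluence_jitter(img, function(n) rep(1, n))
  expect_identical(r1$image, img)
  expect_equal(r1$multiplier, 1)
  r2 <- apply_fluence_jitter(img, function(n) rep(2, n))
  expect_equal(r2$image, 2 * img)
  # log-normal stand-in: sample mean near the analytic mean exp(sdlog^2/2)
  draws <- speckfew:::with_seed(7, fluence_sampler_lognormal(0, 0.6)(1e4))
  expect_lt(abs(mean(draws) - exp(0.18)) / exp(0.18), 0.05)
  expect_error(apply_fluence_jitter(img, function(n) rep(-1, n)),
               "non-positive")
})

test_that("intensity normalization removes scale and handles constants", {
  img <- matrix(rnorm(96 * 96, 5, 3), 96, 96)
  n1 <- normalize_intensity(img)
  expect_equal(normalize_intensity(2 * img), n1, tolerance = 1e-12)
  expect_equal(mean(n1), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(n1)), 1, tolerance = 1e-12)
  expect_identical(normalize_intensity(matrix(3, 5, 5)), matrix(0, 5, 5))
  # unmasked-pixel statistics when a mask is supplied
  m <- matrix(FALSE, 96, 96); m[1:10, ] <- TRUE
  nm <- normalize_intensity(img, mask = m)
  expect_equal(mean(nm[!m]), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(nm[!m])), 1, tolerance = 1e-12)
})
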