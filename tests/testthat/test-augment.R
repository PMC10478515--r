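# Augmentations and the leakage-safe split-before-augment builder.

test_that("rotation: identity, exact 90 degrees, approximate round trip", {
  img <- matrix(runif(20 * 20), 20, 20)
  expect_identical(random_rotation(img, 0), img)
  r90 <- random_rotation(img, 90, interp = "nearest")
  # exact lattice rotation: counter-clockwise quarter turn
  expect_equal(r90, t(img)[rev(seq_len(20)), ])
  expect_equal(random_rotation(r90, 270, interp = "nearest"), img)
  # 37 degrees there and back on a smooth pattern: small error away from
  # the borders (bilinear interpolation cannot round-trip white noise)
  g <- outer(1:20, 1:20, function(i, j) {
    exp(-((i - 10.5)^2 + (j - 10.5)^2) / 30) + 0.3 * sin(i / 3) * cos(j / 4)
  })
  sm <- random_rotation(random_rotation(g, 37), -37)
  core <- 6:15
  err <- mean(abs(sm[core, core] - g[core, core]))
  expect_lt(err, 0.05 * diff(range(g)))
})

test_that("random masking changes only the requested block", {
  img <- matrix(runif(30 * 30), 30, 30) + 1
  expect_identical(random_masking(img, n_blocks = 0L), img)
  m1 <- random_masking(img, 1L, c(10L, 10L), fill = 0, seed = 3)
  expect_identical(m1, random_masking(img, 1L, c(10L, 10L), fill = 0, seed = 3))
  changed <- sum(m1 != img)
  expect_lte(changed, 100L)
  expect_gte(changed, 1L)
  expect_true(all(m1[m1 != img] == 0))
})

test_that("zoom and shift: identities, exactness, area scaling", {
  img <- matrix(runif(24 * 24), 24, 24)
  expect_identical(random_zoom(img, 1), img)
  expect_identical(random_shift(img, 0, 0), img)
  s1 <- random_shift(img, 3, 0)
  back <- random_shift(s1, -3, 0)
  expect_equal(back[4:21, ], img[4:21, ], tolerance = 1e-12)
  # doubling zoom quadruples the area of a centered bright disk
  disk <- matrix(0, 48, 48)
  ctr <- (48 + 1) / 2
  for (i in 1:48) for (j in 1:48) {
    if ((i - ctr)^2 + (j - ctr)^2 <= 36) disk[i, j] <- 1
  }
  z <- random_zoom(disk, 2)
  a0 <- sum(disk > 0.5)
  a2 <- sum(z > 0.5)
  expect_lt(abs(a2 - 4 * a0) / (4 * a0), 0.15)
})

test_that("augmentations preserve shape and produce finite values", {
  img <- matrix(rnorm(20 * 20), 20, 20)
  cfg <- augment_config()
  for (s in 1:5) {
    a <- speckfew:::augment_image(img, cfg, seed = s)
    expect_equal(dim(a), dim(img))
    expect_true(all(is.finite(a)))
  }
})

test_that("split_then_augment partitions sources before augmenting", {
  d <- tiny_patterns(5L)  # 10 sources over 2 classes
  sp <- split_then_augment(d, c(train = 0.5, val = 0.25, test = 0.25),
                           n_augment_per_source = 3L, seed = 1L)
  sizes <- vapply(sp, nrow, 1L)
  # each partition holds its sources x 4 patterns (1 original + 3 augments)
  n_src <- vapply(sp, function(x) sum(!x$is_augmented), 1L)
  expect_equal(sizes, n_src * 4L)
  expect_equal(sum(n_src), 10L)
  expect_true(all(n_src >= 2L))
  expect_true(audit_split(sp))
  # no source id in two partitions
  ids <- lapply(sp, function(x) unique(x$source_id))
  expect_equal(length(Reduce(intersect, ids)), 0L)
})

test_that("plain split uses documented rounding and errors on empty classes", {
  d <- tiny_patterns(4L)  # 8 sources
  sp <- split_then_augment(d, c(train = 0.75, test = 0.25),
                           n_augment_per_source = 0L, seed = 2L)
  expect_equal(nrow(sp$train), 6L)
  expect_equal(nrow(sp$test), 2L)
  expect_error(
    split_then_augment(tiny_patterns(1L), c(train = 0.5, val = 0.25,
                                            test = 0.25)),
    "partition")
})

test_that("a corrupted partition fails the leakage audit", {
  d <- tiny_patterns(4L)
  sp <- split_then_augment(d, c(train = 0.5, test = 0.5),
                           n_augment_per_source = 2L, seed = 3L)
  # move one augmented copy across the boundary
  bad_idx <- which(sp$train$is_augmented)[1]
  sp$test <- dplyr::bind_rows(sp$test, sp$train[bad_idx, ])
  expect_error(audit_split(sp), "leakage")
})
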