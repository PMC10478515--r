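# Triplet machinery: distances, loss, difficulty taxonomy, semi-hard
# selection, and the training loop's contracts.

unitize <- function(M) M / sqrt(rowSums(M^2))

test_that("pairwise squared distances match a double-loop oracle", {
  set.seed(1)
  E <- unitize(matrix(rnorm(10 * 8), 10, 8))
  D <- pairwise_sq_dists(E)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) oracle[i, j] <- sum((E[i, ] - E[j, ])^2)
  expect_lt(max(abs(D - oracle)), 1e-10)
  expect_equal(diag(D), rep(0, 10))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 4 + 1e-12))
  # antipodal unit vectors sit at the distance bound of 4
  u <- c(1, rep(0, 7))
  expect_equal(pairwise_sq_dists(rbind(u, -u))[1, 2], 4)
})

test_that("triplet loss equals the hinge of the margin violation", {
  expect_equal(triplet_loss(0, 4, 0.2), 0)
  expect_equal(triplet_loss(1, 1, 0.3), 0.3)   # identical embeddings -> alpha
  expect_equal(triplet_loss(0.5, 0.6, 0.2), 0.1)
  expect_equal(triplet_loss(c(0, 1, 0.5), c(4, 1, 0.6), 0.2),
               c(0, 0.2, 0.1))
  expect_true(all(triplet_loss(runif(50, 0, 4), runif(50, 0, 4), 0.5) >= 0))
  expect_error(triplet_loss(1, 1, 4.5), "\\(0, 4]")
  expect_error(triplet_loss(1, 1, 0), "\\(0, 4]")
})

test_that("difficulty taxonomy splits at d_ap and d_ap + alpha", {
  expect_equal(classify_triplet_difficulty(1, 0.5, 1), "hard")
  expect_equal(classify_triplet_difficulty(1, 1.5, 1), "semi_hard")
  expect_equal(classify_triplet_difficulty(1, 2.5, 1), "easy")
  # boundary ties are assigned to the closed semi-hard band
  expect_equal(classify_triplet_difficulty(1, 1, 1), "semi_hard")
  expect_equal(classify_triplet_difficulty(1, 2, 1), "semi_hard")
  # easy triplets have zero loss (and hence zero gradient)
  d_ap <- runif(100, 0, 2)
  alpha <- 0.4
  d_an <- d_ap + alpha + runif(100, 1e-9, 1)
  kind <- classify_triplet_difficulty(d_ap, d_an, alpha)
  expect_true(all(kind == "easy"))
  expect_true(all(triplet_loss(d_ap, d_an, alpha) == 0))
})

# Points on the unit circle embedded in d = 8; squared chord distance
# between angles a and b is 2 - 2*cos(a - b).
circle_pt <- function(theta, d = 8L) c(cos(theta), sin(theta), rep(0, d - 2L))

test_that("selector returns exactly the planted semi-hard triplets", {
  alpha <- 1.5
  # anchor/positive pair of class A (same sample) with d_ap = 0.2 between
  # them; class-B negatives placed so that, for either anchor ordering,
  # one is hard, one is semi-hard (the planted target) and two are easy
  th_ap <- acos(1 - 0.2 / 2)
  th_of_d <- function(d) acos(1 - d / 2)
  E <- rbind(circle_pt(0), circle_pt(th_ap),
             circle_pt(6 * pi / 180),    # hard for both anchors
             circle_pt(-th_of_d(0.45)),  # planted semi-hard for both
             circle_pt(pi),              # easy
             circle_pt(-150 * pi / 180)) # easy
  labels <- c("A", "A", "B", "B", "B", "B")
  # class-B points carry distinct sample ids so only the class-A pair can
  # serve as anchor/positive under the multi-sample rule
  samples <- c("s1", "s1", "s2", "s3", "s4", "s5")
  D <- pairwise_sq_dists(E)
  # independent oracle: enumerate every valid triplet and filter
  valid <- list()
  for (a in 1:6) for (p in 1:6) for (n in 1:6) {
    if (a != p && labels[a] == labels[p] && samples[a] == samples[p] &&
        labels[n] != labels[a] &&
        D[a, p] <= D[a, n] && D[a, n] <= D[a, p] + alpha) {
      valid[[length(valid) + 1L]] <- c(a, p, n)
    }
  }
  valid <- do.call(rbind, valid)
  # the only semi-hard negative is point 4 (for either anchor ordering)
  expect_true(all(valid[, 3] == 4L))
  sel <- select_semihard_triplets(E, labels, samples, alpha = alpha,
                                  n_triplets = 20L, seed = 1L)
  expect_true(all(sel$type == "semi_hard"))
  expect_true(all(sel$negative == 4L))
  key <- paste(sel$anchor, sel$positive, sel$negative)
  expect_true(all(key %in% paste(valid[, 1], valid[, 2], valid[, 3])))
  # returned distances satisfy the semi-hard inequality by audit
  expect_true(all(sel$d_ap <= sel$d_an & sel$d_an <= sel$d_ap + alpha))
})

test_that("selector falls back when no semi-hard negative exists", {
  alpha <- 0.2
  # all negatives easy (antipodal): fallback must pick a random valid one
  E_easy <- rbind(circle_pt(0), circle_pt(0.1), -circle_pt(0),
                  -circle_pt(0.05))
  sel <- select_semihard_triplets(E_easy, c("A", "A", "B", "B"),
                                  c("s", "s", "t", "u"), alpha = alpha,
                                  n_triplets = 10L, seed = 2L)
  expect_true(all(sel$type == "fallback_random"))
  expect_true(all(sel$negative %in% 3:4))
  # all negatives hard: fallback takes the easiest hard one (largest d_an)
  th_ap <- acos(1 - 1.0 / 2)
  E_hard <- rbind(circle_pt(0), circle_pt(th_ap),
                  circle_pt(acos(1 - 0.3 / 2)), circle_pt(-acos(1 - 0.6 / 2)))
  sel2 <- select_semihard_triplets(E_hard, c("A", "A", "B", "B"),
                                   c("s", "s", "t", "u"), alpha = alpha,
                                   n_triplets = 10L, seed = 3L)
  anchored1 <- sel2[sel2$anchor == 1L, ]
  expect_true(all(anchored1$type == "fallback_hard"))
  expect_true(all(anchored1$negative == 4L))  # d_an = 0.6 < d_ap = 1
})

test_that("selector enforces label/sample constraints and determinism", {
  set.seed(4)
  E <- unitize(matrix(rnorm(12 * 8), 12, 8))
  labels <- rep(c("A", "B", "C"), each = 4L)
  samples <- rep(c("s1", "s2"), times = 6L)
  s1 <- select_semihard_triplets(E, labels, samples, alpha = 1,
                                 n_triplets = 30L, seed = 5L)
  s2 <- select_semihard_triplets(E, labels, samples, alpha = 1,
                                 n_triplets = 30L, seed = 5L)
  expect_identical(s1, s2)
  expect_true(all(labels[s1$anchor] == labels[s1$positive]))
  expect_true(all(samples[s1$anchor] == samples[s1$positive]))
  expect_true(all(labels[s1$anchor] != labels[s1$negative]))
  expect_true(all(s1$anchor != s1$positive))
  expect_error(select_semihard_triplets(E, rep("A", 12), samples),
               "two classes")
})

test_that("training is reproducible and inert at zero learning rate", {
  d <- preprocess_patterns(tiny_patterns(6L), gaussian_sigma = 0, seed = 1)
  emb <- build_embedder(tiny_model_config(seed = 2L))
  cfg0 <- train_config(epochs = 1L, lr = 0, batch_size = 8L,
                       triplets_per_batch = 4L, seed = 3L)
  fit0 <- fit_embedder(emb, d, d, cfg0)
  expect_equal(fit0$final_embedder$net$params, emb$net$params,
               tolerance = 1e-14)
  cfg <- train_config(epochs = 2L, batch_size = 8L, triplets_per_batch = 4L,
                      seed = 4L)
  f1 <- fit_embedder(emb, d, d, cfg)
  f2 <- fit_embedder(emb, d, d, cfg)
  expect_identical(f1$history, f2$history)
  expect_named(f1$history, c("epoch", "train_loss", "val_loss", "n_fallbacks"))
  expect_error(
    fit_embedder(emb, d, d[d$label == "a", ], cfg),
    "missing class")
})

test_that("tidy and glance summarize a fit", {
  d <- preprocess_patterns(tiny_patterns(4L), gaussian_sigma = 0, seed = 5)
  emb <- build_embedder(tiny_model_config(seed = 6L))
  fit <- fit_embedder(emb, d, d, train_config(epochs = 2L, batch_size = 8L,
                                              triplets_per_batch = 4L,
                                              seed = 7L))
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_equal(g$epochs, 2L)
  expect_true(g$n_parameters > 0)
})
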