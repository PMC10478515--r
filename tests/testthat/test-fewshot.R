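# N-way X-shot classification against labeled supports.

unitv <- function(x) x / sqrt(sum(x^2))

make_support <- function(labels, vectors) {
  speckfew:::as_support(tibble::tibble(
    label = labels, embedding = vectors,
    source_id = paste0("s", seq_along(labels)),
    is_augmented = FALSE))
}

test_that("a query on top of a support is assigned that class", {
  q <- unitv(c(1, rep(0, 7)))
  sup <- make_support(c("A", "A", "B", "B"),
                      list(q, unitv(c(1, 0.1, rep(0, 6))), -q,
                           unitv(c(-1, 0.1, rep(0, 6)))))
  res <- classify(q, sup)
  expect_equal(res$predicted_label, "A")
  expect_true(0 %in% res$per_support$distance)
  expect_lt(res$per_class$mean_distance[res$per_class$label == "A"],
            res$per_class$mean_distance[res$per_class$label == "B"])
})

test_that("exact ties break toward the lexicographically smallest label", {
  q <- unitv(c(1, rep(0, 7)))
  v1 <- unitv(c(0, 1, rep(0, 6)))
  v2 <- unitv(c(0, -1, rep(0, 6)))
  sup <- make_support(c("zeta", "alpha"), list(v1, v2))  # equidistant
  expect_equal(classify(q, sup)$predicted_label, "alpha")
})

test_that("classification matches a brute-force recomputation", {
  set.seed(1)
  for (rep in 1:5) {
    sup_vecs <- lapply(1:15, function(i) unitv(rnorm(128)))
    labels <- rep(c("A", "B", "C"), each = 5L)
    sup <- make_support(labels, sup_vecs)
    q <- unitv(rnorm(128))
    res <- classify(q, sup)
    d <- vapply(sup_vecs, function(v) sqrt(sum((q - v)^2)), numeric(1))
    means <- tapply(d, labels, mean)
    expect_equal(res$per_class$mean_distance,
                 as.vector(means[res$per_class$label]))
    expect_equal(res$predicted_label, names(which.min(means)))
    # squared-distance variant against its own oracle
    res2 <- classify(q, sup, distance = "squared")
    means2 <- tapply(d^2, labels, mean)
    expect_equal(res2$predicted_label, names(which.min(means2)))
  }
})

test_that("prediction is invariant to support permutations", {
  set.seed(2)
  sup_vecs <- lapply(1:10, function(i) unitv(rnorm(16)))
  labels <- rep(c("A", "B"), each = 5L)
  q <- unitv(rnorm(16))
  base <- classify(q, make_support(labels, sup_vecs))$predicted_label
  for (r in 1:5) {
    perm <- sample(10)
    res <- classify(q, make_support(labels[perm], sup_vecs[perm]))
    expect_equal(res$predicted_label, base)
  }
})

test_that("batch classification equals per-query calls", {
  set.seed(3)
  sup <- make_support(rep(c("A", "B"), each = 3L),
                      lapply(1:6, function(i) unitv(rnorm(16))))
  expect_identical(batch_classify(list(), sup), list())
  qs <- lapply(1:20, function(i) unitv(rnorm(16)))
  batch <- batch_classify(qs, sup)
  single <- lapply(qs, classify, support = sup)
  expect_identical(batch, single)
})

test_that("build_support samples X per class, reproducibly", {
  d <- preprocess_patterns(tiny_patterns(5L), gaussian_sigma = 0, seed = 1)
  emb <- build_embedder(tiny_model_config())
  s1 <- build_support(d, emb, shots = 1L, seed = 9L)
  expect_equal(nrow(s1), 2L)
  s3a <- build_support(d, emb, shots = 3L, seed = 10L)
  s3b <- build_support(d, emb, shots = 3L, seed = 10L)
  expect_identical(s3a$source_id, s3b$source_id)
  expect_true(all(abs(vapply(s3a$embedding,
                             function(v) sum(v^2), numeric(1)) - 1) < 1e-5))
  expect_error(build_support(d, emb, shots = 6L), "fewer than 6")
})

test_that("classify_patterns agrees with nearest-class-centroid on
           well-clustered embeddings", {
  # two tight clusters; both routes computed independently
  set.seed(4)
  centers <- list(A = unitv(c(1, rep(0, 15))), B = unitv(c(-1, rep(0, 15))))
  mk <- function(cl, n) {
    lapply(seq_len(n), function(i) {
      unitv(centers[[cl]] + rnorm(16, 0, 0.05))
    })
  }
  sup_vec <- c(mk("A", 8), mk("B", 8))
  sup <- make_support(rep(c("A", "B"), each = 8L), sup_vec)
  queries <- c(mk("A", 25), mk("B", 25))
  truth <- rep(c("A", "B"), each = 25L)
  pred <- vapply(queries, function(q) classify(q, sup)$predicted_label, "")
  centroid_pred <- vapply(queries, function(q) {
    cA <- colMeans(do.call(rbind, sup_vec[1:8]))
    cB <- colMeans(do.call(rbind, sup_vec[9:16]))
    if (sum((q - cA)^2) <= sum((q - cB)^2)) "A" else "B"
  }, "")
  expect_gte(mean(pred == centroid_pred), 0.95)
  expect_equal(pred, truth)
})
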