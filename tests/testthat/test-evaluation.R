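# Metrics, binary relabeling, ablation masks and the t-SNE export.

test_that("confusion matrix and scores on hand-computed cases", {
  truth <- c("a", "a", "b", "b")
  sc <- confusion_and_scores(truth, truth)
  expect_equal(sc$accuracy, 1)
  expect_true(all(sc$per_class_f1$f1 == 1))
  expect_equal(diag(sc$confusion), c(a = 2L, b = 2L))

  # everything predicted "a" on a balanced two-class set:
  # accuracy 1/2, F1(a) = 2 * 1 * 0.5 / 1.5 = 2/3, F1(b) = 0
  sc2 <- confusion_and_scores(truth, rep("a", 4))
  expect_equal(sc2$accuracy, 0.5)
  expect_equal(sc2$per_class_f1$f1, c(2 / 3, 0))
  expect_equal(sc2$macro_f1, 1 / 3)
  expect_equal(sum(sc2$confusion), 4L)
  expect_error(confusion_and_scores(character(0), character(0)), "non-empty")

  # metrics are recomputable bit-exactly from the stored matrix
  cm <- sc2$confusion
  expect_equal(sum(diag(cm)) / sum(cm), sc2$accuracy)
})

test_that("binary relabeling pools non-single classes and is idempotent", {
  x <- c("single_hit", "multi_hit", "non_sample_hit")
  expect_equal(relabel_binary(x),
               c("single_hit", "non_single_hit", "non_single_hit"))
  expect_equal(relabel_binary(rep("single_hit", 3)), rep("single_hit", 3))
  expect_equal(relabel_binary(relabel_binary(x)), relabel_binary(x))
})

test_that("ablation mask keeps a contiguous block of the right area", {
  m <- ablation_mask(96L, 0.25)
  expect_equal(sum(m), floor(0.75 * 96 * 96))
  expect_false(any(m[1:48, 1:48]))
  expect_identical(ablation_mask(96L, 1), matrix(FALSE, 96, 96) | FALSE)
  m2 <- ablation_mask(96L, 0.25, mode = "random", seed = 4L)
  expect_equal(sum(m2), floor(0.75 * 96 * 96))
  expect_identical(m2, ablation_mask(96L, 0.25, mode = "random", seed = 4L))
})

test_that("fraction one reproduces the plain evaluation", {
  d <- preprocess_patterns(
    tiny_patterns(8L, classes = c("single_hit", "multi_hit")),
    gaussian_sigma = 0, seed = 1)
  emb <- build_embedder(tiny_model_config(seed = 2L))
  r1 <- detector_ablation(d, emb, fraction = 1, shots = 2L, seed = 3L)
  # manual plain evaluation with the same support/query split
  r1b <- detector_ablation(d, emb, fraction = 1, shots = 2L, seed = 3L)
  expect_identical(r1, r1b)
  expect_equal(r1$model, "embedding_fewshot")
  expect_true(r1$accuracy >= 0 && r1$accuracy <= 1)
  # masked run changes the inputs but keeps the same pairing
  r2 <- detector_ablation(d, emb, fraction = 0.25, shots = 2L, seed = 3L)
  expect_equal(r2$n_queries, r1$n_queries)
})

test_that("fluence scan covers the grid and a degenerate grid is a plain
           evaluation", {
  g <- tiny_geometry()
  d <- simulate_fringe_classes(8L, geometry = g, masks = NULL,
                               crop_size = 20L, seed = 5L, keep_raw = TRUE,
                               samples_per_class = 2L, n_atoms = 30L)
  emb <- build_embedder(tiny_model_config(input_size = 20L, seed = 6L))
  grid <- experiment_grid(fluence_factors = c(0.1, 1), shots = c(1L, 2L),
                          seed = 7L)
  scan <- fluence_scan(d, emb, grid, masks = NULL, crop_size = 20L)
  expect_equal(nrow(scan), 4L)
  expect_setequal(scan$fluence_factor, c(0.1, 1))
  expect_true(all(scan$accuracy >= 0 & scan$accuracy <= 1))
  expect_true(all(scan$n_queries > 0))
  deg <- fluence_scan(d, emb, experiment_grid(1, 2L, seed = 7L),
                      masks = NULL, crop_size = 20L)
  expect_equal(nrow(deg), 1L)
  base <- scan[scan$fluence_factor == 1 & scan$shots == 2L, ]
  expect_equal(deg$accuracy, base$accuracy)
})

test_that("t-SNE export returns seeded 2-D coordinates", {
  set.seed(8)
  E <- matrix(rnorm(40 * 16), 40, 16)
  E <- E / sqrt(rowSums(E^2))
  p1 <- tsne_export(E, labels = rep(c("x", "y"), 20), seed = 9L,
                    n_iter = 50L)
  expect_equal(dim(p1), c(40L, 3L))
  expect_named(p1, c("x", "y", "label"))
  p2 <- tsne_export(E, labels = rep(c("x", "y"), 20), seed = 9L,
                    n_iter = 50L)
  expect_identical(p1, p2)
  path <- withr::local_tempfile(fileext = ".csv")
  tsne_export(E[1:10, ], path = path, seed = 1L, n_iter = 20L)
  expect_true(file.exists(path))
  expect_equal(nrow(utils::read.csv(path)), 10L)
  expect_error(tsne_export(E[1, , drop = FALSE]), "at least two")
})
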