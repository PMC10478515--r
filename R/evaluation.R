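# Evaluation protocols: confusion matrix / accuracy / F-1, binary
# relabeling for the threshold baseline, the photon-fluence scan, and the
# missing-detector-area ablation.

#' Confusion matrix, accuracy and F-1 scores
#'
#' @param truth,predictions Character vectors of equal, positive length.
#' @param labels Ordered class list; defaults to the sorted union of the
#'   observed labels.
#' @return List with `confusion` (K x K matrix, rows = truth, columns =
#'   prediction), `accuracy`, `per_class_f1` (tibble with precision,
#'   recall, f1; 0 where undefined) and `macro_f1` (unweighted mean).
#' @export
confusion_and_scores <- function(truth, predictions, labels = NULL) {
  if (length(truth) == 0L || length(truth) != length(predictions)) {
    stop("truth and predictions must be non-empty and of equal length")
  }
  labels <- labels %||% sort(unique(c(truth, predictions)))
  cm <- table(factor(truth, levels = labels),
              factor(predictions, levels = labels))
  cm <- matrix(as.integer(cm), length(labels), length(labels),
               dimnames = list(truth = labels, prediction = labels))
  acc <- sum(diag(cm)) / sum(cm)
  per <- purrr::map_dfr(seq_along(labels), function(k) {
    tp <- cm[k, k]
    prec <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    rec <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(label = labels[k], precision = prec, recall = rec, f1 = f1)
  })
  list(confusion = cm, accuracy = acc, per_class_f1 = per,
       macro_f1 = mean(per$f1))
}

#' Relabel hit classes for binary classification
#'
#' Collapses `multi_hit` and `non_sample_hit` to `non_single_hit`,
#' preserving `single_hit`; idempotent.
#'
#' @param labels Character vector.
#' @return Relabeled vector.
#' @export
relabel_binary <- function(labels) {
  ifelse(labels == "single_hit", "single_hit", "non_single_hit")
}

#' Experiment grid for the fluence scan
#'
#' @param fluence_factors Intensity scaling factors applied to test
#'   patterns before the noise chain; default `10^-2 ... 10^2` in steps of
#'   `10^0.5`.
#' @param shots Few-shot scenario sizes (default 1, 5, 20).
#' @param detector_fraction Fraction of the crop area available.
#' @param seed Integer seed.
#' @return An object of class `speckle_grid`.
#' @export
experiment_grid <- function(fluence_factors = 10^seq(-2, 2, by = 0.5),
                            shots = c(1L, 5L, 20L),
                            detector_fraction = 1,
                            seed = 1L) {
  assert_positive(fluence_factors, "fluence_factors")
  stopifnot(all(shots >= 1L), detector_fraction > 0, detector_fraction <= 1)
  structure(list(fluence_factors = fluence_factors,
                 shots = as.integer(shots),
                 detector_fraction = detector_fraction,
                 seed = as.integer(seed)),
            class = "speckle_grid")
}

#' Photon-fluence scan
#'
#' For every fluence scaling factor, the noise-free test patterns are
#' rescaled, run through the noise chain (shot noise, masks, crop,
#' normalization, Gaussian noise) and classified in each N-way X-shot
#' scenario; supports are drawn from the same rescaled pool, disjoint from
#' the queries.
#'
#' @param raw_data Pattern tibble generated with `keep_raw = TRUE` (the
#'   `image_raw` column holds noise-free, unmasked, uncropped intensities).
#' @param embedder Trained `speckle_embedder`.
#' @param grid An [experiment_grid()].
#' @param masks,crop_size,gaussian_sigma Noise-chain settings (must match
#'   the training conditions).
#' @return Tibble with one row per (factor, shots) cell: accuracy,
#'   macro F-1 and the number of queries.
#' @export
fluence_scan <- function(raw_data, embedder, grid = experiment_grid(),
                         masks = NULL, crop_size = 96L,
                         gaussian_sigma = 0.15) {
  if (is.null(raw_data$image_raw)) {
    stop("raw_data must carry an image_raw column (simulate with keep_raw = TRUE)")
  }
  max_shots <- max(grid$shots)
  cells <- list()
  for (f in grid$fluence_factors) {
    finished <- raw_data
    finished$image <- purrr::imap(raw_data$image_raw, function(raw, i) {
      finish_image(raw, masks, crop_size,
                   derive_seed(grid$seed, "scanshot", signif(f, 6), i),
                   factor = f)
    })
    finished$image_raw <- NULL
    finished <- preprocess_patterns(finished, gaussian_sigma,
                                    derive_seed(grid$seed, "scangauss",
                                                signif(f, 6)))
    if (grid$detector_fraction < 1) {
      am <- ablation_mask(crop_size, grid$detector_fraction)
      finished$image <- lapply(finished$image, apply_masks, masks = am)
    }
    # disjoint support pool and query set
    sup_idx <- with_seed(derive_seed(grid$seed, "support", signif(f, 6)), {
      unlist(lapply(sort(unique(finished$label)), function(cl) {
        i <- which(finished$label == cl)
        i[sample.int(length(i), min(max_shots, length(i)))]
      }))
    })
    pool <- finished[sup_idx, , drop = FALSE]
    queries <- finished[-sup_idx, , drop = FALSE]
    for (x in grid$shots) {
      support <- build_support(pool, embedder, shots = x,
                               seed = derive_seed(grid$seed, "shots", x))
      pred <- classify_patterns(queries, embedder, support)
      sc <- confusion_and_scores(pred$label, pred$predicted_label,
                                 sort(unique(raw_data$label)))
      cells[[length(cells) + 1L]] <- tibble::tibble(
        fluence_factor = f, shots = x, accuracy = sc$accuracy,
        macro_f1 = sc$macro_f1, n_queries = nrow(queries))
    }
  }
  out <- dplyr::bind_rows(cells)
  class(out) <- c("speckle_fluence_scan", class(out))
  out
}

#' Ablation mask for missing detector area
#'
#' Keeps a contiguous square region covering `fraction` of the crop
#' (top-left by default, emulating the loss of detector panels) and masks
#' the rest. For `fraction = 0.25` on a 96x96 crop this keeps the 48x48
#' top-left quadrant, masking exactly 75% of the pixels.
#'
#' @param size Crop edge length.
#' @param fraction Fraction of area kept, in (0, 1].
#' @param mode `"fixed"` (top-left) or `"random"` corner.
#' @param seed Seed for `mode = "random"`.
#' @return Logical matrix, `TRUE` = masked.
#' @export
ablation_mask <- function(size, fraction, mode = c("fixed", "random"),
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction <= 1)
  size <- as.integer(size)
  keep <- round(size * sqrt(fraction))
  m <- matrix(TRUE, size, size)
  corner <- if (mode == "fixed") c(1L, 1L) else {
    with_seed(seed, {
      rs <- sample(c(1L, size - keep + 1L), 2L, replace = TRUE)
      rs
    })
  }
  m[corner[1]:(corner[1] + keep - 1L), corner[2]:(corner[2] + keep - 1L)] <- FALSE
  m
}

#' Missing-detector-area ablation
#'
#' Masks all but a `fraction` of each crop on every query AND support
#' pattern, then evaluates (a) the embedding few-shot classifier and (b)
#' the probability-threshold binary baseline on the same masked inputs,
#' giving a paired robustness comparison. Metrics for the embedding model
#' are computed on binary-relabeled predictions so both models are scored
#' on the same task.
#'
#' @param test Preprocessed pattern tibble with hit-class labels.
#' @param embedder Trained `speckle_embedder`.
#' @param baseline Trained `speckle_baseline` (or `NULL` to skip).
#' @param fraction Fraction of detector area available (1 = no ablation).
#' @param shots Few-shot size for the embedding classifier (default 5).
#' @param mode,seed Passed to [ablation_mask()]; `seed` also draws the
#'   support set.
#' @return Tibble with one row per model: accuracy and macro F-1 on the
#'   binary task, plus the fraction evaluated.
#' @export
detector_ablation <- function(test, embedder, baseline = NULL, fraction = 1,
                              shots = 5L, mode = "fixed", seed = 1L) {
  size <- nrow(test$image[[1]])
  data <- test
  if (fraction < 1) {
    am <- ablation_mask(size, fraction, mode, seed)
    data$image <- lapply(data$image, apply_masks, masks = am)
  }
  # embedding classifier: support drawn from the (masked) test pool
  sup_idx <- with_seed(derive_seed(seed, "absupport"), {
    unlist(lapply(sort(unique(data$label)), function(cl) {
      i <- which(data$label == cl)
      i[sample.int(length(i), min(shots, length(i)))]
    }))
  })
  pool <- data[sup_idx, , drop = FALSE]
  queries <- data[-sup_idx, , drop = FALSE]
  support <- build_support(pool, embedder, shots = shots,
                           seed = derive_seed(seed, "abshots"))
  pred <- classify_patterns(queries, embedder, support)
  sc_e <- confusion_and_scores(relabel_binary(pred$label),
                               relabel_binary(pred$predicted_label),
                               c("non_single_hit", "single_hit"))
  rows <- tibble::tibble(model = "embedding_fewshot", fraction = fraction,
                         accuracy = sc_e$accuracy, macro_f1 = sc_e$macro_f1,
                         n_queries = nrow(queries))
  if (!is.null(baseline)) {
    bp <- predict_baseline(queries, baseline)
    sc_b <- confusion_and_scores(relabel_binary(bp$label), bp$pred_binary,
                                 c("non_single_hit", "single_hit"))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      model = "threshold_baseline", fraction = fraction,
      accuracy = sc_b$accuracy, macro_f1 = sc_b$macro_f1,
      n_queries = nrow(queries)))
  }
  rows
}
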