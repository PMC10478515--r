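# The package's two benchmark protocols, fixed study conditions that the
# acceptance tests and scripts/acceptance.R both run. Problem sizes are
# chosen for desk-scale reproduction (see the methods vignette).

#' Few-shot learning benchmark on separable synthetic classes
#'
#' Simulates a two-class dataset with distinct fringe spacings (about 200
#' patterns per class at 96 x 96 by default), trains the embedder, and
#' measures held-out N-way X-shot accuracy at baseline fluence for 1, 5
#' and 20 shots, plus an optional low-fluence scan cell. Bootstrap
#' standard errors of the shot-to-shot accuracy differences quantify the
#' sampling noise of the ordering.
#'
#' @param seed Master seed for the whole protocol.
#' @param n_per_class Patterns per class (default 200).
#' @param epochs Training epochs (default 5).
#' @param shots Few-shot scenarios (default 1, 5, 20).
#' @param extra_fluence_factors Additional fluence scaling factors to
#'   evaluate at 5 shots (default 0.01, the signal-starved end).
#' @param n_boot Bootstrap replicates for accuracy differences.
#' @return List with `metrics` (tibble shots/accuracy/n_queries),
#'   `ordering` (tibble of consecutive-shot accuracy differences with
#'   bootstrap standard errors), `scan` (extra fluence cells), `fit`.
#' @export
protocol_fewshot_learning <- function(seed = 1L, n_per_class = 200L,
                                      epochs = 5L, shots = c(1L, 5L, 20L),
                                      extra_fluence_factors = 0.01,
                                      n_boot = 200L) {
  geometry <- detector_geometry()
  masks <- mask_set(geometry)
  d <- simulate_fringe_classes(n_per_class, geometry = geometry,
                               masks = masks, keep_raw = TRUE,
                               seed = derive_seed(seed, "data"))
  sp <- split_then_augment(d, c(train = 0.6, val = 0.2, test = 0.2),
                           n_augment_per_source = 0L,
                           seed = derive_seed(seed, "split"))
  tr <- preprocess_patterns(sp$train, 0.15, derive_seed(seed, "pp", "tr"))
  va <- preprocess_patterns(sp$val, 0.15, derive_seed(seed, "pp", "va"))
  te <- preprocess_patterns(sp$test, 0.15, derive_seed(seed, "pp", "te"))

  emb <- build_embedder(model_config(seed = derive_seed(seed, "init")))
  fit <- fit_embedder(emb, tr, va,
                      train_config(epochs = epochs,
                                   seed = derive_seed(seed, "train")))

  # disjoint support pool / queries from the held-out test partition
  max_shots <- max(shots)
  sup_idx <- with_seed(derive_seed(seed, "suppool"), {
    unlist(lapply(sort(unique(te$label)), function(cl) {
      i <- which(te$label == cl)
      i[sample.int(length(i), min(max_shots, length(i)))]
    }))
  })
  pool <- te[sup_idx, , drop = FALSE]
  queries <- te[-sup_idx, , drop = FALSE]

  correct <- list()
  metrics <- list()
  for (x in shots) {
    support <- build_support(pool, fit$embedder, shots = x,
                             seed = derive_seed(seed, "support", x))
    pred <- classify_patterns(queries, fit$embedder, support)
    ok <- pred$label == pred$predicted_label
    correct[[as.character(x)]] <- ok
    metrics[[length(metrics) + 1L]] <- tibble::tibble(
      shots = x, accuracy = mean(ok), n_queries = length(ok))
  }
  metrics <- dplyr::bind_rows(metrics)

  # bootstrap the consecutive accuracy differences over queries
  nq <- nrow(queries)
  ordering <- purrr::map_dfr(seq_len(length(shots) - 1L), function(k) {
    lo <- correct[[as.character(shots[k])]]
    hi <- correct[[as.character(shots[k + 1L])]]
    diffs <- with_seed(derive_seed(seed, "boot", k), {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(nq, nq, replace = TRUE)
        mean(hi[i]) - mean(lo[i])
      }, numeric(1))
    })
    tibble::tibble(from_shots = shots[k], to_shots = shots[k + 1L],
                   diff = mean(hi) - mean(lo), boot_se = stats::sd(diffs))
  })

  scan <- NULL
  if (length(extra_fluence_factors) > 0L) {
    scan <- fluence_scan(sp$test, fit$embedder,
                         experiment_grid(extra_fluence_factors, 5L,
                                         seed = derive_seed(seed, "scan")),
                         masks = masks, crop_size = 96L)
  }
  list(metrics = metrics, ordering = ordering, scan = scan, fit = fit)
}

#' Missing-detector-area robustness benchmark
#'
#' The single-sample (online-style) comparison: three hit classes are
#' simulated from one particle, split 50/25/25 before augmentation, and
#' expanded with the two online augmentations (random in-plane rotation
#' and random masking). The embedding classifier (5-shot) and the
#' probability-threshold binary baseline are trained on the same data and
#' evaluated on identical test inputs, once with the full crop and once
#' with only a fraction of the detector area available on every query and
#' support.
#'
#' @param seed Master seed.
#' @param n_per_class Source patterns per class (default 80, giving 40
#'   training and 20 validation sources per class as in a
#'   label-starved online setting).
#' @param epochs Training epochs for both models.
#' @param n_augment_per_source Augmented copies per source (default 2).
#' @param fraction Detector area available in the ablated condition.
#' @param shots Few-shot size (default 5).
#' @return List with `results` (tibble: model x fraction metrics),
#'   `drops` (accuracy drop per model), `embedder_fit`, `baseline_fit`.
#' @export
protocol_detector_robustness <- function(seed = 1L, n_per_class = 80L,
                                         epochs = 4L,
                                         n_augment_per_source = 2L,
                                         fraction = 0.25, shots = 5L) {
  geometry <- detector_geometry()
  masks <- mask_set(geometry)
  part <- random_particle(100L, 50, seed = derive_seed(seed, "particle"),
                          particle_id = "sample_of_interest")
  d <- simulate_dataset(n_per_class, particles = list(part),
                        geometry = geometry, masks = masks,
                        seed = derive_seed(seed, "data"))
  online_aug <- augment_config(rotation_range = c(-180, 180),
                               mask_fraction_range = c(0, 0.25),
                               zoom_range = c(1, 1), shift_range = c(0, 0))
  sp <- split_then_augment(d, c(train = 0.5, val = 0.25, test = 0.25),
                           config = online_aug,
                           n_augment_per_source = n_augment_per_source,
                           seed = derive_seed(seed, "split"),
                           augment_partitions = c("train", "val"))
  tr <- preprocess_patterns(sp$train, 0.15, derive_seed(seed, "pp", "tr"))
  va <- preprocess_patterns(sp$val, 0.15, derive_seed(seed, "pp", "va"))
  te <- preprocess_patterns(sp$test, 0.15, derive_seed(seed, "pp", "te"))

  emb <- build_embedder(model_config(seed = derive_seed(seed, "einit")))
  efit <- fit_embedder(emb, tr, va,
                       train_config(epochs = epochs, sample_aware = FALSE,
                                    seed = derive_seed(seed, "etrain")))
  bl <- build_binary_baseline(model_config(seed = derive_seed(seed, "binit")))
  bfit <- fit_baseline(bl, tr, va,
                       train_config(epochs = epochs,
                                    seed = derive_seed(seed, "btrain")))

  results <- dplyr::bind_rows(
    detector_ablation(te, efit$embedder, bfit$baseline, fraction = 1,
                      shots = shots, seed = derive_seed(seed, "abl")),
    detector_ablation(te, efit$embedder, bfit$baseline, fraction = fraction,
                      shots = shots, seed = derive_seed(seed, "abl")))
  wide <- tidyr::pivot_wider(results[, c("model", "fraction", "accuracy")],
                             names_from = "fraction",
                             values_from = "accuracy")
  drops <- tibble::tibble(
    model = wide$model,
    accuracy_full = wide[["1"]],
    accuracy_ablated = wide[[as.character(fraction)]],
    drop = wide[["1"]] - wide[[as.character(fraction)]])
  list(results = results, drops = drops, embedder_fit = efit,
       baseline_fit = bfit)
}
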