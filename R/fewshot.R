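# N-way X-shot classification: embed the query and all supports, take
# Euclidean distances from the query to every support, average per class,
# and predict the class with the smallest mean distance.

#' Build a support set
#'
#' Samples `shots` labeled patterns per class without replacement and
#' embeds them.
#'
#' @param data Preprocessed pattern tibble of labeled support candidates.
#' @param embedder A `speckle_embedder`.
#' @param shots Support examples per class (X in N-way X-shot).
#' @param seed Integer seed (sampling is deterministic per seed).
#' @return A `speckle_support`: tibble with columns `label`, `embedding`
#'   (unit vectors) and `source_id` provenance.
#' @export
build_support <- function(data, embedder, shots = 5L, seed = 1L) {
  shots <- as.integer(shots)
  stopifnot(shots >= 1L)
  classes <- sort(unique(data$label))
  if (length(classes) < 2L) stop("support needs at least two classes")
  counts <- table(data$label)
  short <- names(counts)[counts < shots]
  if (length(short) > 0L) {
    stop("class(es) with fewer than ", shots, " patterns: ",
         paste(short, collapse = ", "))
  }
  idx <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      i <- which(data$label == cl)
      i[sample.int(length(i), shots)]
    }))
  })
  sup <- embed_patterns(data[idx, , drop = FALSE], embedder)
  structure(tibble::tibble(label = sup$label, embedding = sup$embedding,
                           source_id = sup$source_id),
            class = c("speckle_support", class(tibble::tibble())))
}

# Support set directly from an embedded tibble (no resampling).
as_support <- function(data) {
  stopifnot(!is.null(data$embedding))
  structure(tibble::tibble(label = data$label, embedding = data$embedding,
                           source_id = data$source_id %||%
                             as.character(seq_len(nrow(data)))),
            class = c("speckle_support", class(tibble::tibble())))
}

#' Classify one query embedding against a support set
#'
#' Four steps: the query and supports are embedded on the unit hypersphere;
#' plain Euclidean distances from the query to every support are computed;
#' distances are averaged per class; the class with the smallest average
#' wins (ties broken toward the lexicographically smallest label).
#' Squared distances (as used by the training loss) are available via
#' `distance = "squared"`; the two can rank classes differently once
#' averaged, which is why plain Euclidean is the default.
#'
#' @param query_embedding Unit-norm numeric vector.
#' @param support A `speckle_support`.
#' @param distance `"euclidean"` (default) or `"squared"`.
#' @return A `speckle_classification`: list with `predicted_label`,
#'   `per_class` (tibble label/mean_distance) and `per_support`
#'   (tibble label/source_id/distance).
#' @export
classify <- function(query_embedding, support,
                     distance = c("euclidean", "squared")) {
  distance <- match.arg(distance)
  stopifnot(inherits(support, "speckle_support"))
  counts <- table(support$label)
  if (length(counts) < 2L) stop("support must contain at least two classes")
  q <- as.numeric(query_embedding)
  S <- do.call(rbind, support$embedding)
  d2 <- rowSums(sweep(S, 2L, q)^2)
  d <- if (distance == "euclidean") sqrt(d2) else d2
  per_support <- tibble::tibble(label = support$label,
                                source_id = support$source_id,
                                distance = d)
  per_class <- dplyr::summarise(dplyr::group_by(per_support, label),
                                mean_distance = mean(distance),
                                .groups = "drop")
  per_class <- dplyr::arrange(per_class, label)  # deterministic tie-break
  pred <- per_class$label[which.min(per_class$mean_distance)]
  structure(list(predicted_label = pred, per_class = per_class,
                 per_support = per_support, distance = distance),
            class = "speckle_classification")
}

#' @export
print.speckle_classification <- function(x, ...) {
  cat("<speckle_classification>", x$predicted_label, "\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-16s mean %s distance %.4f\n", pc$label[i],
                x$distance, pc$mean_distance[i]))
  }
  invisible(x)
}

#' Classify a tibble of patterns
#'
#' Embeds every pattern and classifies each against the support set;
#' element-wise identical to calling [classify()] per query.
#'
#' @param data Preprocessed pattern tibble (queries).
#' @param embedder A `speckle_embedder`.
#' @param support A `speckle_support`.
#' @param distance Passed to [classify()].
#' @return `data` with a `predicted_label` column and one
#'   `dist_<class>` column per support class.
#' @export
classify_patterns <- function(data, embedder, support,
                              distance = c("euclidean", "squared")) {
  distance <- match.arg(distance)
  if (nrow(data) == 0L) {
    data$predicted_label <- character(0)
    return(data)
  }
  emb <- embed_patterns(data, embedder)
  results <- lapply(emb$embedding, classify, support = support,
                    distance = distance)
  data$predicted_label <- vapply(results, `[[`, "", "predicted_label")
  classes <- sort(unique(support$label))
  for (cl in classes) {
    data[[paste0("dist_", cl)]] <- vapply(results, function(r) {
      r$per_class$mean_distance[r$per_class$label == cl]
    }, numeric(1))
  }
  data
}

#' @rdname classify_patterns
#' @param queries List of query embeddings (unit vectors).
#' @return For `batch_classify`: list of `speckle_classification`, one per
#'   query, order preserved.
#' @export
batch_classify <- function(queries, support,
                           distance = c("euclidean", "squared")) {
  distance <- match.arg(distance)
  lapply(queries, classify, support = support, distance = distance)
}
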