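# Triplet-loss training on the unit hypersphere: squared-L2 pairwise
# distances, the hinge triplet loss, the easy/semi-hard/hard taxonomy,
# mini-batch semi-hard selection with the multi-sample anchor/positive
# rule, and the Adam training loop.

#' Pairwise squared L2 distances
#'
#' @param embeddings N x d matrix (rows are embeddings). For unit vectors
#'   every entry lies in `[0, 4]`.
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
pairwise_sq_dists <- function(embeddings) {
  E <- as.matrix(embeddings)
  g <- tcrossprod(E)
  r <- diag(g)
  D <- outer(r, r, `+`) - 2 * g
  D[D < 0] <- 0
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Triplet loss
#'
#' `max(0, d_ap - d_an + alpha)`: zero once the negative is farther from
#' the anchor than the positive by at least the margin. On the unit
#' hypersphere squared distances are bounded by 4, so the largest
#' meaningful margin is `alpha = 4`.
#'
#' @param d_ap,d_an Squared anchor-positive / anchor-negative distances
#'   (vectorized).
#' @param alpha Margin in squared-L2 units, in `(0, 4]`.
#' @return Non-negative loss values.
#' @export
triplet_loss <- function(d_ap, d_an, alpha) {
  check_alpha(alpha)
  pmax(0, d_ap - d_an + alpha)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 4) {
    stop("alpha must lie in (0, 4] (squared-L2 distances of unit vectors ",
         "are bounded by 4)")
  }
  invisible(alpha)
}

#' Classify triplet difficulty
#'
#' `hard` when the negative is closer to the anchor than the positive
#' (`d_an < d_ap`); `easy` when the negative is separated by at least the
#' margin (`d_an > d_ap + alpha`, zero loss and zero gradient); `semi_hard`
#' in the closed band between the two (boundary ties count as semi-hard).
#'
#' @inheritParams triplet_loss
#' @return Character vector in `{"easy", "semi_hard", "hard"}`.
#' @export
classify_triplet_difficulty <- function(d_ap, d_an, alpha) {
  check_alpha(alpha)
  out <- rep("semi_hard", length(d_an))
  out[d_an < d_ap] <- "hard"
  out[d_an > d_ap + alpha] <- "easy"
  out
}

#' Select semi-hard triplets from a mini-batch
#'
#' Repeatedly draws a random anchor/positive pair (same label, and — under
#' the multi-sample scheme — the same sample) and a random negative among
#' the candidates with a different label satisfying the semi-hard
#' condition `d_ap <= d_an <= d_ap + alpha` on the given embeddings. When
#' an anchor/positive pair has no semi-hard negative the fallback picks
#' the easiest hard negative (largest `d_an` among `d_an < d_ap`), else a
#' random valid-label negative; such triplets are flagged in the result.
#'
#' @param embeddings N x d matrix of current embeddings.
#' @param labels Character vector of class labels (>= 2 distinct).
#' @param sample_ids Sample identities; used when `sample_aware = TRUE`.
#' @param alpha Margin, `(0, 4]`.
#' @param n_triplets Number of triplets to return.
#' @param seed Integer seed (selection is deterministic per seed).
#' @param sample_aware Require anchor and positive from the same sample.
#' @return Tibble with columns `anchor`, `positive`, `negative` (row
#'   indices), `d_ap`, `d_an` and `type`
#'   (`semi_hard` / `fallback_hard` / `fallback_random`).
#' @export
select_semihard_triplets <- function(embeddings, labels, sample_ids = NULL,
                                     alpha = 0.2, n_triplets = 16L,
                                     seed = 1L, sample_aware = TRUE) {
  check_alpha(alpha)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("triplet selection needs at least two classes in the batch")
  }
  if (is.null(sample_ids)) sample_ids <- rep("sample", length(labels))
  D <- pairwise_sq_dists(embeddings)
  n <- length(labels)

  same <- outer(labels, labels, `==`)
  if (sample_aware) same <- same & outer(sample_ids, sample_ids, `==`)
  diag(same) <- FALSE
  ap_pairs <- which(same, arr.ind = TRUE)  # (anchor, positive)
  if (nrow(ap_pairs) == 0L) {
    stop("no valid anchor/positive pair: need two patterns with the same ",
         "label", if (sample_aware) " and the same sample" else "")
  }

  with_seed(seed, {
    picks <- ap_pairs[sample.int(nrow(ap_pairs), n_triplets, replace = TRUE),
                      , drop = FALSE]
    res <- vector("list", n_triplets)
    for (t in seq_len(n_triplets)) {
      a <- picks[t, 1L]
      p <- picks[t, 2L]
      d_ap <- D[a, p]
      negs <- which(labels != labels[a])
      d_an <- D[a, negs]
      sh <- negs[d_an >= d_ap & d_an <= d_ap + alpha]
      if (length(sh) > 0L) {
        nidx <- sh[sample.int(length(sh), 1L)]
        type <- "semi_hard"
      } else {
        hard <- negs[d_an < d_ap]
        if (length(hard) > 0L) {
          nidx <- hard[which.max(D[a, hard])]
          type <- "fallback_hard"
        } else {
          nidx <- negs[sample.int(length(negs), 1L)]
          type <- "fallback_random"
        }
      }
      res[[t]] <- c(a, p, nidx, d_ap, D[a, nidx],
                    switch(type, semi_hard = 0, fallback_hard = 1,
                           fallback_random = 2))
    }
    m <- do.call(rbind, res)
    tibble::tibble(anchor = as.integer(m[, 1]), positive = as.integer(m[, 2]),
                   negative = as.integer(m[, 3]), d_ap = m[, 4], d_an = m[, 5],
                   type = c("semi_hard", "fallback_hard",
                            "fallback_random")[m[, 6] + 1])
  })
}

#' Training configuration
#'
#' @param alpha Triplet margin on the squared-L2 scale, `(0, 4]`
#'   (default 0.2).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Patterns per mini-batch.
#' @param epochs Training epochs.
#' @param triplets_per_batch Semi-hard triplets selected per mini-batch.
#' @param sample_aware Multi-sample scheme: anchors and positives must come
#'   from the same sample (use `FALSE` for single-sample online training
#'   data where sample identity is uninformative).
#' @param val_triplets Random triplets used for the validation loss
#'   (selector-independent metric).
#' @param seed Master training seed.
#' @return An object of class `speckle_train_config`.
#' @export
train_config <- function(alpha = 0.2, lr = 1e-3, batch_size = 24L,
                         epochs = 10L, triplets_per_batch = 16L,
                         sample_aware = TRUE, val_triplets = 200L,
                         seed = 1L) {
  check_alpha(alpha)
  stopifnot(lr >= 0, batch_size >= 4L, epochs >= 1L, triplets_per_batch >= 1L)
  structure(list(alpha = alpha, lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 triplets_per_batch = as.integer(triplets_per_batch),
                 sample_aware = isTRUE(sample_aware),
                 val_triplets = as.integer(val_triplets),
                 seed = as.integer(seed)),
            class = "speckle_train_config")
}

# Stratified mini-batches: fill each batch with anchor/positive-compatible
# chunks of 2 patterns drawn from one (class, sample) group at a time
# (one (class) group when sample_aware is off), cycling over classes.
make_batches <- function(labels, sample_ids, batch_size, sample_aware, seed) {
  groups <- if (sample_aware) paste(labels, sample_ids, sep = "\r") else labels
  by_group <- split(seq_along(labels), groups)
  by_group <- by_group[vapply(by_group, length, 1L) >= 2L]
  if (length(by_group) == 0L) {
    stop("no (class, sample) group has two patterns; cannot form ",
         "anchor/positive pairs")
  }
  grp_class <- vapply(strsplit(names(by_group), "\r"), `[`, "", 1L)
  classes <- unique(grp_class)
  with_seed(seed, {
    pool <- lapply(by_group, sample)  # shuffle within groups
    total <- sum(lengths(pool))
    n_batches <- max(1L, floor(total / batch_size))
    batches <- vector("list", n_batches)
    ci <- 0L
    for (b in seq_len(n_batches)) {
      idx <- integer(0)
      guard <- 0L
      while (length(idx) < batch_size && guard < 10L * batch_size) {
        guard <- guard + 1L
        ci <- ci + 1L
        cls <- classes[(ci - 1L) %% length(classes) + 1L]
        cand <- which(grp_class == cls & lengths(pool) >= 2L)
        if (length(cand) == 0L) {
          cand <- which(lengths(pool) >= 2L)
          if (length(cand) == 0L) break
        }
        g <- cand[sample.int(length(cand), 1L)]
        take <- pool[[g]][1:2]
        pool[[g]] <- pool[[g]][-(1:2)]
        idx <- c(idx, take)
      }
      if (length(idx) >= 4L) batches[[b]] <- idx
    }
    batches[!vapply(batches, is.null, TRUE)]
  })
}

# Gradient of the mean hinge triplet loss w.r.t. the embeddings.
# E: d x n (columns are embeddings); triplets index columns.
triplet_grad <- function(E, tr, alpha) {
  d_ap <- colSums((E[, tr$anchor, drop = FALSE] -
                     E[, tr$positive, drop = FALSE])^2)
  d_an <- colSums((E[, tr$anchor, drop = FALSE] -
                     E[, tr$negative, drop = FALSE])^2)
  act <- d_ap - d_an + alpha > 0
  G <- matrix(0, nrow(E), ncol(E))
  nt <- nrow(tr)
  for (t in which(act)) {
    a <- tr$anchor[t]; p <- tr$positive[t]; ng <- tr$negative[t]
    ea <- E[, a]; ep <- E[, p]; en <- E[, ng]
    G[, a] <- G[, a] + 2 * (en - ep) / nt
    G[, p] <- G[, p] + 2 * (ep - ea) / nt
    G[, ng] <- G[, ng] + 2 * (ea - en) / nt
  }
  list(G = G, loss = mean(pmax(0, d_ap - d_an + alpha)))
}

# Mean triplet loss over random valid triplets (selector-independent).
random_triplet_loss <- function(E_rows, labels, sample_ids, alpha, n, seed,
                                sample_aware) {
  with_seed(seed, {
    same <- outer(labels, labels, `==`)
    if (sample_aware) same <- same & outer(sample_ids, sample_ids, `==`)
    diag(same) <- FALSE
    ap <- which(same, arr.ind = TRUE)
    if (nrow(ap) == 0L) return(NA_real_)
    picks <- ap[sample.int(nrow(ap), n, replace = TRUE), , drop = FALSE]
    losses <- vapply(seq_len(n), function(t) {
      a <- picks[t, 1L]; p <- picks[t, 2L]
      negs <- which(labels != labels[a])
      ng <- negs[sample.int(length(negs), 1L)]
      d_ap <- sum((E_rows[a, ] - E_rows[p, ])^2)
      d_an <- sum((E_rows[a, ] - E_rows[ng, ])^2)
      max(0, d_ap - d_an + alpha)
    }, numeric(1))
    mean(losses)
  })
}

#' Train the embedding network with semi-hard triplet loss
#'
#' Each mini-batch is embedded with the current model in inference mode,
#' semi-hard triplets are selected at the mini-batch level, and one Adam
#' step is taken on the mean hinge loss of the selected triplets. The
#' validation loss is the mean triplet loss over fixed random triplets from
#' the validation set; the parameters with the best validation loss are
#' kept as the fitted model.
#'
#' @param embedder A `speckle_embedder` (its current weights are the
#'   starting point).
#' @param train,val Preprocessed pattern tibbles; the validation set must
#'   contain every training class.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `speckle_fit` with elements `embedder` (best validation
#'   weights), `final_embedder`, `history` (tibble: epoch, train_loss,
#'   val_loss, n_fallbacks) and `config`. Supports [tidy()][tidy.speckle_fit]
#'   and [glance()][glance.speckle_fit].
#' @export
fit_embedder <- function(embedder, train, val, config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(embedder, "speckle_embedder"))
  missing_cls <- setdiff(unique(train$label), unique(val$label))
  if (length(missing_cls) > 0L) {
    stop("validation set is missing class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain at least two classes")
  }

  Xtr <- pattern_matrix(train)
  Xval <- pattern_matrix(val)
  ws <- ws_get(embedder, capacity = config$batch_size)

  history <- vector("list", config$epochs)
  best <- list(val = Inf, params = NULL, state = NULL, epoch = 0L)

  for (ep in seq_len(config$epochs)) {
    batches <- make_batches(train$label, train$sample_id, config$batch_size,
                            config$sample_aware,
                            derive_seed(config$seed, "batches", ep))
    ep_losses <- numeric(0)
    ep_fallbacks <- 0L
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      Xb <- Xtr[, idx, drop = FALSE]
      # selection pass: current model, inference mode
      E_sel <- cpp_ws_forward(ws, Xb, FALSE)
      tr <- select_semihard_triplets(
        t(E_sel), train$label[idx], train$sample_id[idx],
        alpha = config$alpha, n_triplets = config$triplets_per_batch,
        seed = derive_seed(config$seed, "select", ep, bi),
        sample_aware = config$sample_aware)
      ep_fallbacks <- ep_fallbacks + sum(tr$type != "semi_hard")
      # training pass + gradient step
      E <- cpp_ws_forward(ws, Xb, TRUE)
      tg <- triplet_grad(E, tr, config$alpha)
      ep_losses <- c(ep_losses, tg$loss)
      cpp_ws_backward(ws, tg$G)
      cpp_ws_adam_step(ws, config$lr, 0.9, 0.999, 1e-8)
    }
    # validation under current weights
    snap_params <- cpp_ws_get_params(ws)
    snap_state <- cpp_ws_get_state(ws)
    Eval <- ws_forward_chunked(ws, Xval, config$batch_size)
    val_loss <- random_triplet_loss(t(Eval), val$label, val$sample_id,
                                    config$alpha, config$val_triplets,
                                    derive_seed(config$seed, "valtrip"),
                                    sample_aware = FALSE)
    if (is.finite(val_loss) && val_loss < best$val) {
      best <- list(val = val_loss, params = snap_params, state = snap_state,
                   epoch = ep)
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, train_loss = mean(ep_losses), val_loss = val_loss,
      n_fallbacks = ep_fallbacks)
    if (verbose) {
      message(sprintf("epoch %d | train %.4f | val %.4f | fallbacks %d",
                      ep, mean(ep_losses), val_loss, ep_fallbacks))
    }
  }

  final <- embedder
  final$net$params <- lapply(cpp_ws_get_params(ws), strip_dim_vec)
  final$net$state <- lapply(cpp_ws_get_state(ws), as.vector)
  final$env <- new.env(parent = emptyenv())

  best_model <- embedder
  if (!is.null(best$params)) {
    best_model$net$params <- lapply(best$params, strip_dim_vec)
    best_model$net$state <- lapply(best$state, as.vector)
  } else {
    best_model <- final
    best$epoch <- config$epochs
  }
  best_model$env <- new.env(parent = emptyenv())

  structure(list(embedder = best_model, final_embedder = final,
                 history = dplyr::bind_rows(history), config = config,
                 best_epoch = best$epoch),
            class = "speckle_fit")
}

ws_forward_chunked <- function(ws, X, batch) {
  n <- ncol(X)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch))
  do.call(cbind, lapply(chunks, function(ix) {
    cpp_ws_forward(ws, X[, ix, drop = FALSE], FALSE)
  }))
}

#' Tidy a fitted embedder's training history
#'
#' @param x A `speckle_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.speckle_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `speckle_fit`.
#' @param ... Unused.
#' @return Tibble with epochs, best epoch/validation loss, final training
#'   loss and parameter count.
#' @export
glance.speckle_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_loss, na.rm = TRUE),
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_parameters = sum(vapply(x$embedder$net$params, length, numeric(1))))
}

#' @export
print.speckle_fit <- function(x, ...) {
  g <- glance.speckle_fit(x)
  cat(sprintf(
    "<speckle_fit> %d epochs | best val loss %.4f (epoch %d) | final train loss %.4f\n",
    g$epochs, g$best_val_loss, g$best_epoch, g$final_train_loss))
  invisible(x)
}

#' Train the binary baseline classifier
#'
#' Binary cross-entropy training of the probability-threshold baseline on
#' `single_hit` vs everything else (apply [relabel_binary()] semantics
#' internally), with the same Adam settings as the embedder.
#'
#' @param baseline A `speckle_baseline`.
#' @param train,val Preprocessed pattern tibbles.
#' @param config A [train_config()] (`alpha`, `triplets_per_batch` and
#'   `sample_aware` are ignored).
#' @param verbose Print per-epoch progress.
#' @return A list with `baseline` (best validation weights) and `history`.
#' @export
fit_baseline <- function(baseline, train, val, config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(baseline, "speckle_baseline"))
  ytr <- as.numeric(train$label == "single_hit")
  yval <- as.numeric(val$label == "single_hit")
  if (length(unique(ytr)) < 2L) {
    stop("baseline training needs both single-hit and non-single-hit patterns")
  }
  Xtr <- pattern_matrix(train)
  Xval <- pattern_matrix(val)
  ws <- ws_get(baseline, capacity = config$batch_size)
  n <- ncol(Xtr)
  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  history <- vector("list", config$epochs)
  best <- list(val = Inf, params = NULL, state = NULL, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, "bl", ep), sample.int(n))
    starts <- seq.int(1L, n, config$batch_size)
    ep_losses <- numeric(0)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next
      p <- as.vector(cpp_ws_forward(ws, Xtr[, idx, drop = FALSE], TRUE))
      y <- ytr[idx]
      ep_losses <- c(ep_losses, bce(p, y))
      dz <- matrix((p - y) / length(idx), 1L)  # d(BCE)/d(pre-sigmoid)
      cpp_ws_backward(ws, dz)
      cpp_ws_adam_step(ws, config$lr, 0.9, 0.999, 1e-8)
    }
    pv <- as.vector(ws_forward_chunked(ws, Xval, config$batch_size))
    val_loss <- bce(pv, yval)
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = cpp_ws_get_params(ws),
                   state = cpp_ws_get_state(ws), epoch = ep)
    }
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = mean(ep_losses),
                                    val_loss = val_loss)
    if (verbose) {
      message(sprintf("baseline epoch %d | train %.4f | val %.4f",
                      ep, mean(ep_losses), val_loss))
    }
  }
  out <- baseline
  if (!is.null(best$params)) {
    out$net$params <- lapply(best$params, strip_dim_vec)
    out$net$state <- lapply(best$state, as.vector)
  }
  out$env <- new.env(parent = emptyenv())
  list(baseline = out, history = dplyr::bind_rows(history),
       best_epoch = best$epoch)
}
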