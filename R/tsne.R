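# Exact (O(N^2)) t-SNE, used only as a 2-D diagnostic export of the
# embedding space. Implemented here because no t-SNE package ships with
# the package's dependency set; the exact formulation is adequate for the
# few hundred embeddings a diagnostic plot shows.

tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1e-12, length(di)) else p <- p / sp
      H <- -sum(p * log(pmax(p, 1e-12)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Export a 2-D t-SNE projection of embeddings
#'
#' Diagnostic visualization of the embedding space; writes (and returns) a
#' table of 2-D coordinates with labels. Deterministic per seed.
#'
#' @param embeddings N x d matrix (or embedded pattern tibble).
#' @param labels Optional labels (taken from the tibble if present).
#' @param path Optional CSV output path.
#' @param perplexity t-SNE perplexity (reduced automatically for tiny N).
#' @param n_iter Gradient-descent iterations.
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `y`, `label`.
#' @export
tsne_export <- function(embeddings, labels = NULL, path = NULL,
                        perplexity = 15, n_iter = 300L, seed = 1L) {
  if (is.data.frame(embeddings)) {
    labels <- labels %||% embeddings$label
    embeddings <- embedding_matrix(embeddings)
  }
  X <- as.matrix(embeddings)
  n <- nrow(X)
  if (n < 2L) stop("t-SNE needs at least two points")
  labels <- labels %||% rep(NA_character_, n)
  perplexity <- min(perplexity, floor((n - 1) / 3) + 1)
  D2 <- pairwise_sq_dists(X)
  P <- tsne_affinities(D2, perplexity)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2L))
  gain <- matrix(1, n, 2L)
  inc <- matrix(0, n, 2L)
  momentum <- 0.5
  eta <- 100
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100L) 4 else 1     # early exaggeration
    sumY <- rowSums(Y * Y)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    G <- 4 * (diag(rowSums(W)) - W) %*% Y
    gain <- pmax(0.01, ifelse(sign(G) != sign(inc), gain + 0.2, gain * 0.8))
    inc <- momentum * inc - eta * gain * G
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
    if (it == 50L) momentum <- 0.8
  }
  out <- tibble::tibble(x = Y[, 1], y = Y[, 2], label = labels)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
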