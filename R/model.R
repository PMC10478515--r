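# User-facing model objects. A `speckle_embedder` wraps the network
# parameters plus architecture; heavy forward/backward passes run in a
# persistent compiled workspace (allocated once and reused, see
# src/net.cpp) that is cached in an environment slot and never serialized.

#' Embedding-network configuration
#'
#' Architecture of the vision backbone: two valid 5x5 convolutions (stride
#' 1, no padding), each followed by ReLU, batch normalization and 2x2
#' max pooling with stride 2, then two fully connected layers producing an
#' embedding that is divided by its L2 norm, so every pattern lands on the
#' unit hypersphere. For a 96x96 input the spatial chain is
#' 96 -> 92 -> 46 -> 42 -> 21.
#'
#' @param conv1_out_channels,conv2_out_channels Convolution widths
#'   (default 32 each; the second layer's filters then span 32 input
#'   channels).
#' @param fc_hidden Width of the hidden fully connected layer.
#' @param embed_dim Embedding dimension (default 128).
#' @param input_size Input image edge length (default 96; minimum 16).
#' @param init_mean,init_std Gaussian weight initialization parameters
#'   (default N(0, 0.2^2)).
#' @param seed Initialization seed.
#' @return An object of class `speckle_model_config`.
#' @export
model_config <- function(conv1_out_channels = 32L, conv2_out_channels = 32L,
                         fc_hidden = 512L, embed_dim = 128L,
                         input_size = 96L, init_mean = 0, init_std = 0.2,
                         seed = 1L) {
  stopifnot(conv1_out_channels >= 1, conv2_out_channels >= 1,
            fc_hidden >= 1, embed_dim >= 2, init_std > 0)
  net_size_chain(as.integer(input_size))  # errors if too small
  structure(list(conv1_out_channels = as.integer(conv1_out_channels),
                 conv2_out_channels = as.integer(conv2_out_channels),
                 fc_hidden = as.integer(fc_hidden),
                 embed_dim = as.integer(embed_dim),
                 input_size = as.integer(input_size),
                 init_mean = init_mean, init_std = init_std,
                 seed = as.integer(seed)),
            class = "speckle_model_config")
}

new_model <- function(config, head, out_dim, cls) {
  net <- nn_build(config$input_size, config$conv1_out_channels,
                  config$conv2_out_channels, config$fc_hidden,
                  out_dim, head,
                  config$init_mean, config$init_std, config$seed)
  structure(list(net = net, config = config, env = new.env(parent = emptyenv())),
            class = c(cls, "speckle_model"))
}

#' Build the unit-hypersphere embedding network
#'
#' @param config A [model_config()].
#' @return A `speckle_embedder`: maps preprocessed images to `embed_dim`
#'   unit vectors whose similarity is measured by (squared) L2 distance.
#' @export
build_embedder <- function(config = model_config()) {
  new_model(config, "l2norm", config$embed_dim, "speckle_embedder")
}

#' Build the probability-threshold binary baseline
#'
#' A classifier in the style of earlier CNN hit finders: the same
#' convolutional backbone coupled to fully connected layers ending in a
#' sigmoid that outputs `P(single_hit)`; a pattern is called single-hit
#' when that probability reaches the threshold (0.9 by convention).
#'
#' @param config A [model_config()].
#' @param threshold Probability threshold for the single-hit call.
#' @return A `speckle_baseline` model object.
#' @export
build_binary_baseline <- function(config = model_config(), threshold = 0.9) {
  m <- new_model(config, "sigmoid", 1L, "speckle_baseline")
  m$threshold <- threshold
  m
}

#' Re-initialize model weights
#'
#' Draws every convolutional and fully connected weight i.i.d. from
#' `N(init_mean, init_std^2)`; biases restart at zero and batch-norm
#' scale/offset at 1/0, with running statistics reset.
#'
#' @param model A `speckle_embedder` or `speckle_baseline`.
#' @param seed Integer seed; the same seed reproduces identical weights.
#' @return The re-initialized model.
#' @export
init_weights <- function(model, seed) {
  cfg <- model$config
  a <- model$net$arch
  model$net <- nn_build(cfg$input_size, cfg$conv1_out_channels,
                        cfg$conv2_out_channels, cfg$fc_hidden,
                        a$out_dim, a$head, cfg$init_mean, cfg$init_std,
                        as.integer(seed))
  ws_invalidate(model)
  model
}

## ---- compiled workspace cache -----------------------------------------

WS_BATCH_DEFAULT <- 24L

ws_invalidate <- function(model) {
  model$env$ws <- NULL
  invisible(model)
}

# Get (or create) the compiled workspace and sync the R-side parameters in.
ws_get <- function(model, capacity = WS_BATCH_DEFAULT, sync = TRUE) {
  a <- model$net$arch
  env <- model$env
  if (is.null(env$ws) || env$capacity < capacity) {
    env$ws <- cpp_ws_create(a$input_size, a$C1, a$C2, a$fc_hidden,
                            a$out_dim, a$head == "l2norm",
                            as.integer(max(capacity, WS_BATCH_DEFAULT)))
    env$capacity <- max(capacity, WS_BATCH_DEFAULT)
    sync <- TRUE
  }
  if (sync) {
    cpp_ws_set_params(env$ws, model$net$params)
    cpp_ws_set_state(env$ws, model$net$state)
  }
  env$ws
}

# Pull parameters/state out of the workspace into the R-side model.
ws_pull <- function(model) {
  ws <- model$env$ws
  if (!is.null(ws)) {
    model$net$params <- lapply(cpp_ws_get_params(ws), strip_dim_vec)
    model$net$state <- lapply(cpp_ws_get_state(ws), as.vector)
  }
  model
}

# The compiled side returns 1-column matrices for bias/scale vectors;
# flatten those back to plain vectors (weight matrices are never 1-column
# for any supported width).
strip_dim_vec <- function(x) {
  if (is.matrix(x) && ncol(x) == 1L) as.vector(x) else x
}

## ---- inference --------------------------------------------------------

# Forward a (pixels x N) matrix through the model in inference mode,
# chunked to the workspace capacity. Returns out_dim x N.
model_forward <- function(model, X, batch = WS_BATCH_DEFAULT) {
  ws <- ws_get(model, capacity = batch)
  n <- ncol(X)
  out <- matrix(NA_real_, model$net$arch$out_dim, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    out[, i:j] <- cpp_ws_forward(ws, X[, i:j, drop = FALSE], FALSE)
    i <- j + 1L
  }
  out
}

#' Embed speckle patterns
#'
#' Maps each (preprocessed) pattern through the embedding network and adds
#' an `embedding` list-column of unit vectors to the tibble.
#'
#' @param data Pattern tibble (run [preprocess_patterns()] first).
#' @param embedder A trained or untrained `speckle_embedder`.
#' @return `data` with an `embedding` list-column.
#' @export
embed_patterns <- function(data, embedder) {
  stopifnot(inherits(embedder, "speckle_embedder"))
  if (nrow(data) == 0L) {
    data$embedding <- list()
    return(data)
  }
  E <- model_forward(embedder, pattern_matrix(data))
  data$embedding <- lapply(seq_len(ncol(E)), function(j) E[, j])
  data
}

# N x d matrix from an embedded tibble (rows are patterns).
embedding_matrix <- function(data) {
  stopifnot(!is.null(data$embedding))
  do.call(rbind, data$embedding)
}

#' Baseline single-hit probabilities
#'
#' Runs the binary baseline on each pattern and returns the tibble with
#' columns `p_single` and `pred_binary` (`"single_hit"` when
#' `p_single >= threshold`, else `"non_single_hit"`).
#'
#' @param data Pattern tibble (preprocessed).
#' @param baseline A `speckle_baseline`.
#' @param threshold Probability threshold; defaults to the model's own.
#' @return `data` with prediction columns.
#' @export
predict_baseline <- function(data, baseline, threshold = NULL) {
  stopifnot(inherits(baseline, "speckle_baseline"))
  threshold <- threshold %||% baseline$threshold
  p <- as.vector(model_forward(baseline, pattern_matrix(data)))
  data$p_single <- p
  data$pred_binary <- ifelse(p >= threshold, "single_hit", "non_single_hit")
  data
}

#' @export
print.speckle_model <- function(x, ...) {
  a <- x$net$arch
  np <- sum(vapply(x$net$params, length, numeric(1)))
  cat(sprintf(
    "<%s> input %dx%d | conv %d/%d ch | fc %d -> %d | %s head | %s parameters\n",
    class(x)[1], a$input_size, a$input_size, a$C1, a$C2, a$fc_hidden,
    a$out_dim, a$head, format(np, big.mark = ",")))
  invisible(x)
}
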