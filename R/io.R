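# Checkpoint I/O. A checkpoint is a single-file R serialization holding
# the model parameters, batch-norm running statistics, the architecture
# configuration (also as a JSON string for external inspection), the
# training seed and the package version. The compiled workspace is never
# serialized; it is rebuilt on load.

#' Save / load a model checkpoint
#'
#' @param model A `speckle_embedder`, `speckle_baseline` or `speckle_fit`
#'   (for a fit, the best-validation embedder is stored together with the
#'   training history).
#' @param path Checkpoint file path.
#' @return `path` invisibly for save; the restored object for load.
#' @export
save_checkpoint <- function(model, path) {
  payload <- if (inherits(model, "speckle_fit")) {
    list(kind = "fit", net = model$embedder$net,
         config = model$embedder$config, threshold = NULL,
         history = model$history, train_config = model$config,
         best_epoch = model$best_epoch)
  } else if (inherits(model, "speckle_model")) {
    list(kind = class(model)[1], net = model$net, config = model$config,
         threshold = model$threshold)
  } else {
    stop("cannot checkpoint an object of class ", class(model)[1])
  }
  payload$format <- "speckfew_checkpoint"
  payload$version <- 1L
  payload$package_version <- as.character(utils::packageVersion("speckfew"))
  payload$config_json <- jsonlite::toJSON(unclass(payload$config),
                                          auto_unbox = TRUE, digits = NA)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "speckfew_checkpoint")) {
    stop(path, " is not a speckle checkpoint")
  }
  cfg <- x$config
  class(cfg) <- "speckle_model_config"
  rebuild <- function(cls) {
    m <- if (cls == "speckle_baseline") {
      build_binary_baseline(cfg, threshold = x$threshold %||% 0.9)
    } else {
      build_embedder(cfg)
    }
    m$net$params <- x$net$params
    m$net$state <- x$net$state
    m
  }
  if (identical(x$kind, "fit")) {
    emb <- rebuild("speckle_embedder")
    structure(list(embedder = emb, final_embedder = emb,
                   history = x$history, config = x$train_config,
                   best_epoch = x$best_epoch),
              class = "speckle_fit")
  } else {
    rebuild(x$kind)
  }
}

#' Write evaluation results
#'
#' Writes a result tibble as CSV and, optionally, a JSON summary with the
#' run seed embedded, so a run is reconstructible from its outputs.
#'
#' @param results Tibble of results.
#' @param path CSV output path.
#' @param json_path Optional JSON output path.
#' @param meta Named list of metadata (seeds, config) for the JSON summary.
#' @return `path` invisibly.
#' @export
write_results <- function(results, path, json_path = NULL, meta = list()) {
  utils::write.csv(results, path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(meta = meta, results = results), json_path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
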