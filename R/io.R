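#' Model checkpoints
#'
#' A checkpoint is a single RDS file holding the named parameter tensors
#' (the quantum layer's angles under the name `qdi.theta`) plus the
#' backbone/head specs and seed, accompanied by a human-readable JSON
#' sidecar (`<path>.json`) recording the configuration, the class
#' convention and package version.
#'
#' @param fit A `steatoq_fit` or `steatoq_model`.
#' @param path Checkpoint file path (conventionally `.rds`).
#' @return `load_checkpoint()` returns a `steatoq_model` with the stored
#'   weights.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "steatoq_fit")) fit$model else fit
  stopifnot(inherits(model, "steatoq_model"))
  obj <- list(weights = nn_weights(model$net),
              backbone = model$backbone,
              head = model$head,
              seed = model$seed)
  saveRDS(obj, path)
  sidecar <- list(
    backbone = list(kind = model$backbone$kind,
                    output_dim = model$backbone$output_dim,
                    input_px = model$backbone$input_px),
    head = list(kind = model$head$kind),
    qdi = if (model$head$kind == "hybrid") {
      list(n_qubits = model$head$qdi$n_qubits,
           n_reupload_blocks = model$head$qdi$n_reupload_blocks,
           entangler = model$head$qdi$entangler,
           readout = model$head$qdi$readout_observable)
    },
    seed = model$seed,
    class_convention = "positive class = not_suitable (grades 2-3); a false negative predicts a diseased liver suitable",
    package_version = as.character(utils::packageVersion("steatoq")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$backbone, obj$head, seed = obj$seed)
  model$net <- nn_set_weights(model$net, obj$weights)
  model
}

#' Run configuration files
#'
#' A single YAML file with blocks `data`, `model`, `train`, `federated`
#' and `eval`; absent keys fall back to package defaults. Every CLI run
#' writes a resolved copy of its configuration next to its outputs.
#'
#' @param path YAML file path (`NULL` gives the pure defaults).
#' @return Nested named list of configuration blocks.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    data = list(n_per_grade = 50L, side_px = 32L, crop_px = NULL,
                n_confounders = c(0L, 2L), seed = 1L),
    model = list(head = "hybrid", backbone = "tiny-test-cnn",
                 output_dim = 64L, n_qubits = 5L, n_reupload_blocks = 20L,
                 entangler = "chain"),
    train = list(epochs = 30L, lr = 1e-3, batch_size = 32L, folds = 5L,
                 split_ratio = 0.8, lambda_fn = 1, seed = 1L),
    federated = list(clients = 4L, samples_per_client = 250L, rounds = 15L,
                     local_epochs = 1L, seed = 1L),
    eval = list(test_size = 400L))
  if (is.null(path)) {
    return(defaults)
  }
  user <- yaml::read_yaml(path)
  for (blk in names(user)) {
    if (!blk %in% names(defaults)) {
      defaults[[blk]] <- user[[blk]]
    } else {
      for (key in names(user[[blk]])) {
        defaults[[blk]][[key]] <- user[[blk]][[key]]
      }
    }
  }
  defaults
}

#' @rdname read_run_config
#' @param config Nested configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

model_spec_from_config <- function(cfg) {
  bb <- backbone_spec(cfg$model$backbone, output_dim = cfg$model$output_dim,
                      input_px = cfg$data$side_px)
  head <- if (identical(cfg$model$head, "classical")) {
    classical_head_spec(bb$output_dim)
  } else {
    hybrid_head_spec(bb$output_dim,
                     qdi = qdi_config(cfg$model$n_qubits,
                                      cfg$model$n_reupload_blocks,
                                      cfg$model$entangler))
  }
  list(backbone = bb, head = head)
}

sq_log <- function(..., logfile = NULL) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [steatoq] ",
                 paste0(..., collapse = ""))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
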