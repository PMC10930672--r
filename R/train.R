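#' Training configuration
#'
#' Defaults follow the centralized training recipe: 30 epochs of Adam and
#' five-fold cross-validation with an 8:2 train/test split. The optimizer
#' hyperparameters are standard Adam defaults (the originals were tuned by
#' a search that is out of scope here).
#'
#' @param epochs Number of training epochs (default 30).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param batch_size Minibatch size.
#' @param folds Folds for cross-validation (default 5).
#' @param split_ratio Train fraction of the train/test split (default 0.8).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 30L, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, batch_size = 32L, folds = 5L,
                         split_ratio = 0.8, seed = 1L) {
  epochs <- as.integer(epochs)
  folds <- as.integer(folds)
  if (epochs < 0L) stop("epochs must be >= 0")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(epochs = epochs, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, batch_size = as.integer(batch_size),
                 folds = folds, split_ratio = split_ratio,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param lambda_fn Penalty multiplier for the not-suitable class in the
#'   weighted cross-entropy (1 = unweighted).
#' @export
loss_spec <- function(lambda_fn = 1) {
  if (lambda_fn <= 0) stop("lambda_fn must be positive")
  structure(list(lambda_fn = lambda_fn), class = "loss_spec")
}

#' In-memory labeled tile dataset
#'
#' @param images Array `(N, px, px, 3)` of RGB values in `[0, 1]`.
#' @param labels Vector of binary suitability labels: integers 1/2 or
#'   strings `"suitable"` / `"not_suitable"`.
#' @param meta Optional data frame of per-tile metadata (N rows).
#' @return A `tile_dataset`.
#' @export
tile_dataset <- function(images, labels, meta = NULL) {
  if (length(dim(images)) != 4L) stop("images must be a (N, px, px, 3) array")
  y <- class_index(labels)
  if (dim(images)[1] != length(y)) stop("images and labels disagree on N")
  if (!is.null(meta) && nrow(meta) != length(y)) {
    stop("meta must have one row per tile")
  }
  structure(list(images = images, labels = y, meta = meta),
            class = "tile_dataset")
}

#' @export
print.tile_dataset <- function(x, ...) {
  cat("<tile_dataset> ", length(x$labels), " tiles (",
      sum(x$labels == 1L), " suitable / ", sum(x$labels == 2L),
      " not-suitable), ", dim(x$images)[2], "px\n", sep = "")
  invisible(x)
}

#' @rdname tile_dataset
#' @param dataset A `tile_dataset`.
#' @param idx Integer indices of tiles to keep.
#' @export
dataset_subset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "tile_dataset"))
  tile_dataset(dataset$images[idx, , , , drop = FALSE],
               dataset$labels[idx],
               if (!is.null(dataset$meta)) dataset$meta[idx, , drop = FALSE])
}

#' @rdname tile_dataset
#' @param ratio Train fraction.
#' @param seed Integer seed for the split.
#' @return `holdout_split()`: list with `train` and `test` datasets, split
#'   stratified by class.
#' @export
holdout_split <- function(dataset, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "tile_dataset"))
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  for (cls in 1:2) {
    ids <- which(dataset$labels == cls)
    n_test <- round(length(ids) * (1 - ratio))
    test_idx <- c(test_idx, sample(ids, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(dataset$labels), test_idx)
  list(train = dataset_subset(dataset, train_idx),
       test = dataset_subset(dataset, test_idx))
}

# deterministic per-epoch seed stream, shared by the centralized and
# federated paths so that 1-client FL reproduces centralized training
epoch_seed <- function(base_seed, epoch_index) {
  as.integer((as.numeric(base_seed) + 7919 * epoch_index) %% 2147483647)
}

# One or more epochs of minibatch Adam on an existing model/optimizer pair.
# epoch_offset shifts the seed stream (federated rounds continue it).
train_epochs <- function(model, opt, dataset, epochs, cfg, loss,
                         epoch_offset = 0L) {
  n <- length(dataset$labels)
  history <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    set.seed(epoch_seed(cfg$seed, epoch_offset + e))
    order <- sample.int(n)
    starts <- seq(1L, n, cfg$batch_size)
    tot_loss <- 0
    pred <- integer(n)
    for (s in starts) {
      idx <- order[s:min(s + cfg$batch_size - 1L, n)]
      xb <- dataset$images[idx, , , , drop = FALSE]
      yb <- dataset$labels[idx]
      fw <- nn_forward(model$net, xb, training = TRUE)
      lz <- softmax_wce(fw$out, yb, loss$lambda_fn)
      bw <- nn_backward(model$net, fw$caches, lz$grad)
      st <- adam_step(model$net, bw$grads, opt, lr = cfg$lr,
                      beta1 = cfg$beta1, beta2 = cfg$beta2, eps = cfg$eps)
      model$net <- st$model
      opt <- st$state
      tot_loss <- tot_loss + lz$loss * length(idx)
      pred[idx] <- max.col(lz$probs)
    }
    truth <- dataset$labels
    history[[e]] <- data.frame(
      epoch = epoch_offset + e, split = "train",
      loss = tot_loss / n,
      accuracy = mean(pred == truth),
      fn_rate = if (any(truth == 2L)) {
        mean(pred[truth == 2L] == 1L)
      } else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(model = model, opt = opt,
       history = do.call(rbind, c(history, list(make.row.names = FALSE))))
}

#' Train a suitability classifier
#'
#' Builds the model from its specs with the configured seed and runs
#' minibatch Adam with the class-weighted cross-entropy. With
#' `epochs = 0` the initialized model is returned with an empty history.
#'
#' @param dataset A [tile_dataset()] with both classes present.
#' @param model_spec List with elements `backbone` ([backbone_spec()]) and
#'   `head` ([hybrid_head_spec()] or [classical_head_spec()]).
#' @param config A [train_config()].
#' @param loss A [loss_spec()].
#' @param validation Optional `tile_dataset` evaluated after every epoch.
#' @return A `steatoq_fit`: list with the trained `model`, a `history` data
#'   frame (columns epoch, split, loss, accuracy, fn_rate) and the configs.
#' @export
train_model <- function(dataset, model_spec = default_model_spec(dataset),
                        config = train_config(), loss = loss_spec()) {
  stopifnot(inherits(dataset, "tile_dataset"))
  n <- length(dataset$labels)
  if (n == 0L) stop("dataset is empty")
  if (length(unique(dataset$labels)) < 2L) {
    stop("dataset must contain both classes")
  }
  model <- build_model(model_spec$backbone, model_spec$head,
                       seed = config$seed)
  opt <- adam_init(model$net)
  if (config$epochs == 0L) {
    return(structure(list(model = model,
                          history = empty_history(),
                          config = config, loss = loss),
                     class = "steatoq_fit"))
  }
  tr <- train_epochs(model, opt, dataset, config$epochs, config, loss)
  structure(list(model = tr$model, history = tr$history, config = config,
                 loss = loss),
            class = "steatoq_fit")
}

empty_history <- function() {
  data.frame(epoch = integer(0), split = character(0), loss = numeric(0),
             accuracy = numeric(0), fn_rate = numeric(0),
             stringsAsFactors = FALSE)
}

#' @rdname train_model
#' @param dataset A `tile_dataset` used to pick a matching input size.
#' @export
default_model_spec <- function(dataset) {
  px <- dim(dataset$images)[2]
  bb <- backbone_spec("tiny-test-cnn", input_px = px)
  list(backbone = bb,
       head = hybrid_head_spec(bb$output_dim,
                               qdi = qdi_config()))
}

#' @export
print.steatoq_fit <- function(x, ...) {
  cat("<steatoq_fit> ", x$model$head$kind, " model, ",
      nrow(x$history), " logged epochs\n", sep = "")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train loss %.4f, accuracy %.3f, fn_rate %s\n",
                last$loss, last$accuracy, format(last$fn_rate)))
  }
  invisible(x)
}

#' K-fold cross-validation of a model specification
#'
#' Stratified fold assignment; each fold trains on the remaining folds and
#' is evaluated on the held-out one.
#'
#' @inheritParams train_model
#' @param folds Number of folds (defaults to `config$folds`).
#' @return Data frame with one row per fold: fold, accuracy, fn_rate.
#' @export
cross_validate <- function(dataset, model_spec = default_model_spec(dataset),
                           config = train_config(), loss = loss_spec(),
                           folds = config$folds) {
  stopifnot(inherits(dataset, "tile_dataset"))
  set.seed(config$seed)
  fold_of <- integer(length(dataset$labels))
  for (cls in 1:2) {
    ids <- sample(which(dataset$labels == cls))
    fold_of[ids] <- rep_len(seq_len(folds), length(ids))
  }
  rows <- lapply(seq_len(folds), function(f) {
    cfg <- config
    cfg$seed <- epoch_seed(config$seed, 1000L + f)
    fit <- train_model(dataset_subset(dataset, which(fold_of != f)),
                       model_spec, cfg, loss)
    ev <- evaluate(fit$model, dataset_subset(dataset, which(fold_of == f)))
    data.frame(fold = f, accuracy = ev$accuracy, fn_rate = ev$fn_rate)
  })
  do.call(rbind, rows)
}
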