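#' Evaluate a classifier on a labeled test set
#'
#' The positive (penalized) class is "not suitable": a false negative is a
#' diseased, grade 2-3 liver predicted suitable, and
#' `fn_rate = FN / actual not-suitable` (the miss rate). If the test set
#' lacks not-suitable tiles the fn_rate is reported as `NA` with a warning.
#'
#' @param model A `steatoq_model` (or `steatoq_fit`).
#' @param test A [tile_dataset()]; must be non-empty.
#' @param batch_size Prediction batch size.
#' @return An `eval_report`: list with `confusion` (2x2 integer matrix,
#'   rows = truth suitable/not-suitable, columns = predicted), `accuracy`,
#'   `fn_rate` and `n`.
#' @export
evaluate <- function(model, test, batch_size = 64L) {
  if (inherits(model, "steatoq_fit")) model <- model$model
  stopifnot(inherits(model, "steatoq_model"), inherits(test, "tile_dataset"))
  n <- length(test$labels)
  if (n == 0L) stop("test set is empty")
  pred <- integer(n)
  for (s in seq(1L, n, batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    p <- predict_proba(model, test$images[idx, , , , drop = FALSE])
    pred[idx] <- max.col(p)
  }
  report_from_predictions(test$labels, pred)
}

report_from_predictions <- function(truth, pred) {
  cm <- matrix(0L, 2, 2,
               dimnames = list(truth = c("suitable", "not_suitable"),
                               predicted = c("suitable", "not_suitable")))
  for (t in 1:2) {
    for (p in 1:2) cm[t, p] <- sum(truth == t & pred == p)
  }
  fn_rate <- if (sum(cm[2, ]) > 0L) {
    cm[2, 1] / sum(cm[2, ])
  } else {
    warning("no not-suitable tiles in the test set; fn_rate is undefined")
    NA_real_
  }
  structure(list(confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm),
                 fn_rate = fn_rate,
                 n = sum(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n,
      sprintf(" accuracy = %.4f  fn_rate = %s\n", x$accuracy,
              format(x$fn_rate)))
  print(x$confusion)
  invisible(x)
}

#' Penalty-weight sweep (lambda sweep)
#'
#' Cross-validates the model at each value of the false-negative penalty
#' lambda and reports mean and standard deviation of accuracy and fn_rate
#' across folds, mirroring the bar-chart view of accuracy versus lambda.
#'
#' @param grid Numeric vector of lambda values (e.g. `1:10`).
#' @param dataset A [tile_dataset()].
#' @param model_spec Backbone + head specs as in [train_model()].
#' @param config A [train_config()]; `config$folds` folds are used.
#' @param out_csv Optional path; when given the table is also written as
#'   CSV.
#' @return Data frame with columns lambda, accuracy_mean, accuracy_sd,
#'   fn_rate_mean, fn_rate_sd.
#' @export
lambda_sweep <- function(grid, dataset,
                         model_spec = default_model_spec(dataset),
                         config = train_config(), out_csv = NULL) {
  if (length(grid) == 0L) stop("lambda grid must be non-empty")
  rows <- lapply(grid, function(lam) {
    cv <- cross_validate(dataset, model_spec, config, loss_spec(lam))
    data.frame(lambda = lam,
               accuracy_mean = mean(cv$accuracy),
               accuracy_sd = stats::sd(cv$accuracy),
               fn_rate_mean = mean(cv$fn_rate),
               fn_rate_sd = stats::sd(cv$fn_rate))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Training-set-size sweep
#'
#' Trains both the hybrid and the classical model on nested subsamples of
#' increasing size and evaluates every run on one fixed held-out test set,
#' tracing the learning curve of accuracy against training-set size.
#' Subsamples are nested (each smaller training set is a subset of the
#' larger ones) to reduce variance along the curve.
#'
#' @param sizes Integer vector of training-set sizes.
#' @param dataset Pool [tile_dataset()]; must hold `max(sizes) + test_size`
#'   tiles.
#' @param test_size Number of tiles held out once for all runs
#'   (default 400).
#' @param config A [train_config()].
#' @param loss A [loss_spec()].
#' @param out_csv Optional CSV path.
#' @return Data frame with columns size, model, accuracy, fn_rate.
#' @export
train_size_sweep <- function(sizes, dataset, test_size = 400L,
                             config = train_config(), loss = loss_spec(),
                             out_csv = NULL) {
  n <- length(dataset$labels)
  need <- max(sizes) + test_size
  if (n < need) {
    stop("pool too small: need ", need, " tiles, have ", n)
  }
  set.seed(config$seed)
  test_idx <- sort(unlist(lapply(1:2, function(cls) {
    sample(which(dataset$labels == cls), test_size %/% 2L)
  })))
  test <- dataset_subset(dataset, test_idx)
  pool_idx <- setdiff(seq_len(n), test_idx)
  # one stratified shuffled order; size-s training sets are its prefixes
  set.seed(epoch_seed(config$seed, 17L))
  pool_idx <- pool_idx[order(sample(length(pool_idx)))]
  px <- dim(dataset$images)[2]
  bb <- backbone_spec("tiny-test-cnn", input_px = px)
  specs <- list(
    hybrid = list(backbone = bb, head = hybrid_head_spec(bb$output_dim)),
    classical = list(backbone = bb, head = classical_head_spec(bb$output_dim))
  )
  rows <- list()
  for (s in sort(sizes)) {
    train <- dataset_subset(dataset, pool_idx[seq_len(s)])
    for (kind in names(specs)) {
      fit <- train_model(train, specs[[kind]], config, loss)
      ev <- evaluate(fit, test)
      rows[[length(rows) + 1L]] <-
        data.frame(size = s, model = kind, accuracy = ev$accuracy,
                   fn_rate = ev$fn_rate)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Reassemble tile predictions into a slide heatmap
#'
#' The tiling step records each tile's (row, col) grid position; this tool
#' maps per-tile probabilities of the not-suitable class back onto the
#' slide grid with a diverging blue-white-red colormap (blue = healthy,
#' red = diseased). Grid cells without a prediction are rendered neutral
#' gray.
#'
#' @param tile_predictions Data frame with columns `row`, `col` (1-based
#'   grid coordinates) and `prob` (probability not-suitable in `[0, 1]`).
#' @param grid_shape Integer vector `c(rows, cols)` of the tile grid.
#' @param cell_px Pixel side of each rendered cell.
#' @return RGB array `(rows * cell_px, cols * cell_px, 3)` in `[0, 1]`.
#' @export
reassemble_heatmap <- function(tile_predictions, grid_shape, cell_px = 16L) {
  stopifnot(all(c("row", "col", "prob") %in% names(tile_predictions)))
  gr <- as.integer(grid_shape[1])
  gc <- as.integer(grid_shape[2])
  r <- as.integer(tile_predictions$row)
  cl <- as.integer(tile_predictions$col)
  if (any(r < 1L | r > gr | cl < 1L | cl > gc)) {
    stop("tile coordinates outside the grid")
  }
  if (anyDuplicated(cbind(r, cl))) {
    stop("duplicate tile coordinates in predictions")
  }
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  img <- array(0.5, c(gr, gc, 3))
  cols <- ramp(pmin(pmax(tile_predictions$prob, 0), 1)) / 255
  for (i in seq_along(r)) img[r[i], cl[i], ] <- cols[i, ]
  # upscale by pixel replication
  img[rep(seq_len(gr), each = cell_px), rep(seq_len(gc), each = cell_px), ,
      drop = FALSE]
}
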