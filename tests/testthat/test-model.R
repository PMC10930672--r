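# small in-memory datasets shared by the training tests
tiny_ds <- function(n_per_grade = 15L, side = 16L, seed = 3L) {
  synth_dataset(n_per_grade, side_px = side, seed = seed)
}

test_that("parameter counts are exact", {
  expect_identical(count_parameters(qdi_config())$total, 105L)
  expect_identical(count_parameters(qdi_config(1, 1))$total, 2L)

  # single-affine 1000 -> 100 pre-layer, 5-qubit QDI, 5 -> 2 post-layer
  head <- hybrid_head_spec(1000L, fc_pre = 100L)
  counts <- count_parameters(head)
  expect_identical(counts$fc_pre, 100100L)
  expect_identical(counts$qdi, 105L)
  expect_identical(counts$fc_post, 12L)
  expect_identical(counts$total, 100217L)

  # a built tiny hybrid model agrees with the head arithmetic
  bb <- backbone_spec(input_px = 16)
  model <- build_model(bb, hybrid_head_spec(bb$output_dim), seed = 1)
  built <- count_parameters(model)
  expect_identical(built$qdi, 105)
  expect_identical(as.integer(built$head),
                   count_parameters(hybrid_head_spec(bb$output_dim))$total)
})

test_that("forward pass produces normalized, deterministic probabilities", {
  bb <- backbone_spec(input_px = 16)
  model <- build_model(bb, hybrid_head_spec(bb$output_dim), seed = 42)
  set.seed(5)
  x <- array(runif(6 * 16 * 16 * 3), c(6, 16, 16, 3))
  p <- predict_proba(model, x)
  expect_equal(dim(p), c(6L, 2L))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0))

  # duplicated inputs give identical rows
  x2 <- x
  x2[2, , , ] <- x[1, , , ]
  p2 <- predict_proba(model, x2)
  expect_identical(p2[1, ], p2[2, ])

  # same seed -> bit-identical weights and logits across two builds
  model_b <- build_model(bb, hybrid_head_spec(bb$output_dim), seed = 42)
  expect_identical(steatoq:::nn_weights(model$net),
                   steatoq:::nn_weights(model_b$net))
  expect_identical(predict_proba(model_b, x), p)

  expect_error(predict_proba(model, array(0, c(2, 8, 8, 3))), "batch")
})

test_that("backbone/head construction validates its inputs", {
  expect_error(build_model(backbone_spec("pretrained-resnet18")), "offline")
  expect_error(build_model(backbone_spec(output_dim = 32),
                           hybrid_head_spec(64)), "match")
  expect_error(hybrid_head_spec(64, fc_pre = c(50)), "capacity")
})

test_that("network layer gradients match finite differences", {
  # a miniature full hybrid stack on random data: checks conv, pool, dense,
  # tanh squash and QDI backward wiring end to end
  bb <- backbone_spec(input_px = 12, output_dim = 8)
  head <- hybrid_head_spec(8, fc_pre = 4L, qdi = qdi_config(2, 2))
  model <- build_model(bb, head, seed = 7)
  set.seed(8)
  x <- array(runif(3 * 12 * 12 * 3), c(3, 12, 12, 3))
  y <- c(1L, 2L, 1L)
  fw <- steatoq:::nn_forward(model$net, x, training = TRUE)
  lz <- steatoq:::softmax_wce(fw$out, y, 2)
  bw <- steatoq:::nn_backward(model$net, fw$caches, lz$grad)
  h <- 1e-5
  loss_at <- function(m) {
    out <- steatoq:::nn_forward(m$net, x)$out
    steatoq:::softmax_wce(out, y, 2)$loss
  }
  # probe a handful of coordinates in every parameterized layer
  set.seed(9)
  for (i in seq_along(model$net$layers)) {
    for (nm in names(model$net$layers[[i]]$params)) {
      p <- model$net$layers[[i]]$params[[nm]]
      for (probe in sample(length(p), min(3, length(p)))) {
        mp <- model
        mp$net$layers[[i]]$params[[nm]][probe] <- p[probe] + h
        mm <- model
        mm$net$layers[[i]]$params[[nm]][probe] <- p[probe] - h
        fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
        expect_equal(bw$grads[[i]][[nm]][probe], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  ds <- tiny_ds()
  spec <- list(backbone = backbone_spec(input_px = 16),
               head = classical_head_spec(64))
  cfg <- train_config(epochs = 5, seed = 21, batch_size = 16)
  fit <- train_model(ds, spec, cfg, loss_spec(1))
  expect_identical(nrow(fit$history), 5L)
  expect_lt(fit$history$loss[5], fit$history$loss[1])

  fit2 <- train_model(ds, spec, cfg, loss_spec(1))
  expect_identical(fit$history, fit2$history)
  expect_identical(steatoq:::nn_weights(fit$model$net),
                   steatoq:::nn_weights(fit2$model$net))
})

test_that("epochs = 0 returns the initialized model with empty history", {
  ds <- tiny_ds()
  spec <- list(backbone = backbone_spec(input_px = 16),
               head = classical_head_spec(64))
  fit <- train_model(ds, spec, train_config(epochs = 0, seed = 2))
  expect_identical(nrow(fit$history), 0L)
  ref <- build_model(spec$backbone, spec$head, seed = 2)
  expect_identical(steatoq:::nn_weights(fit$model$net),
                   steatoq:::nn_weights(ref$net))
})

test_that("degenerate datasets are rejected", {
  ds <- tiny_ds()
  one_class <- dataset_subset(ds, which(ds$labels == 1L))
  spec <- list(backbone = backbone_spec(input_px = 16),
               head = classical_head_spec(64))
  expect_error(train_model(one_class, spec), "both classes")
  empty <- dataset_subset(ds, integer(0))
  expect_error(train_model(empty, spec), "empty")
})

test_that("loss gradient flows into the quantum head", {
  bb <- backbone_spec(input_px = 16)
  model <- build_model(bb, hybrid_head_spec(bb$output_dim), seed = 31)
  set.seed(32)
  x <- array(runif(8 * 16 * 16 * 3), c(8, 16, 16, 3))
  y <- rep(1:2, 4)
  fw <- steatoq:::nn_forward(model$net, x, training = TRUE)
  lz <- steatoq:::softmax_wce(fw$out, y, 1)
  bw <- steatoq:::nn_backward(model$net, fw$caches, lz$grad)
  types <- vapply(model$net$layers, function(l) l$type, character(1))
  qdi_i <- which(types == "qdi")
  expect_gt(max(abs(bw$grads[[qdi_i]]$theta)), 1e-8)
})

test_that("checkpoints round-trip weights and predictions", {
  ds <- tiny_ds(8)
  spec <- list(backbone = backbone_spec(input_px = 16),
               head = hybrid_head_spec(64, qdi = qdi_config(3, 4)))
  fit <- train_model(ds, spec, train_config(epochs = 1, seed = 6))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$qdi$n_qubits, 3L)
  restored <- load_checkpoint(path)
  expect_identical(steatoq:::nn_weights(restored$net),
                   steatoq:::nn_weights(fit$model$net))
  x <- ds$images[1:4, , , , drop = FALSE]
  expect_identical(predict_proba(restored, x), predict_proba(fit$model, x))
})
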