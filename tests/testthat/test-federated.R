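test_that("partition arithmetic matches the hospital scenario", {
  # 4000 balanced samples over 32 clients -> 125 each; over 4 -> 1000 each
  manifest <- build_balanced_dataset(1000, render = FALSE, seed = 2)
  for (ncl in c(32L, 4L)) {
    part <- partition_dataset(manifest,
                              fl_config(n_clients = ncl,
                                        samples_per_client = 4000L %/% ncl,
                                        seed = 5))
    expect_length(part, ncl)
    sizes <- lengths(part)
    expect_true(all(sizes == 4000L %/% ncl))
    all_ids <- unname(unlist(part))
    expect_identical(anyDuplicated(all_ids), 0L) # disjoint
    y <- steatoq:::class_index(manifest$label)
    for (shard in part) {
      # balanced up to the parity of the shard size (125 splits 62/63)
      expect_lte(abs(sum(y[shard] == 1L) - sum(y[shard] == 2L)), 1L)
    }
  }
})

test_that("patient-disjoint partitions keep patients on one client", {
  manifest <- build_balanced_dataset(100, render = FALSE, seed = 3)
  part <- partition_dataset(manifest,
                            fl_config(n_clients = 4, samples_per_client = 80,
                                      seed = 8))
  owner <- rep(NA_integer_, length(unique(manifest$patient_id)))
  names(owner) <- unique(manifest$patient_id)
  for (k in seq_along(part)) {
    pats <- unique(manifest$patient_id[part[[k]]])
    expect_true(all(is.na(owner[pats]))) # not seen on another client
    owner[pats] <- k
  }
})

test_that("partition failures are explicit", {
  manifest <- build_balanced_dataset(10, render = FALSE)
  expect_error(partition_dataset(manifest,
                                 fl_config(n_clients = 4,
                                           samples_per_client = 50)),
               "insufficient")
  # single client absorbing everything: union of shards = input
  part <- partition_dataset(manifest,
                            fl_config(n_clients = 1,
                                      samples_per_client = 40))
  expect_identical(sort(unname(unlist(part))), seq_len(40L))
})

test_that("fedavg computes the size-weighted mean and checks schemas", {
  w1 <- list(a = matrix(0, 2, 2), b = c(0, 0))
  w2 <- list(a = matrix(4, 2, 2), b = c(4, 4))

  # idempotence on identical inputs
  same <- fedavg_aggregate(list(w1, w1, w1))
  expect_identical(same, w1)

  # equal counts -> arithmetic mean
  eq <- fedavg_aggregate(list(w1, w2))
  expect_equal(eq$a, matrix(2, 2, 2))

  # counts (1, 3): (1*0 + 3*4) / 4 = 3
  wt <- fedavg_aggregate(list(w1, w2), sample_counts = c(1, 3))
  expect_equal(wt$a, matrix(3, 2, 2))
  expect_equal(wt$b, c(3, 3))

  bad <- list(a = matrix(1, 2, 2))
  expect_error(fedavg_aggregate(list(w1, bad)), "schema")
  expect_error(fedavg_aggregate(list(w1, list(a = matrix(1, 3, 3),
                                              b = c(1, 1)))),
               "shape|schema")
  expect_error(fedavg_aggregate(list()), "at least one")
})

test_that("one-client federated run reproduces centralized training", {
  ds <- synth_dataset(25, side_px = 16, seed = 19) # 100 tiles
  spec <- list(backbone = backbone_spec(input_px = 16),
               head = classical_head_spec(64))
  tc <- train_config(epochs = 3, seed = 23)
  central <- train_model(ds, spec, tc, loss_spec(1))
  fl <- run_federated(ds, spec,
                      fl_config(n_clients = 1, samples_per_client = 100,
                                rounds = 1, local_epochs = 3, seed = 23),
                      tc, loss_spec(1))
  expect_identical(steatoq:::nn_weights(central$model$net),
                   steatoq:::nn_weights(fl$model$net))
})

test_that("zero rounds returns the initialized global model", {
  ds <- synth_dataset(10, side_px = 16, seed = 29)
  spec <- list(backbone = backbone_spec(input_px = 16),
               head = classical_head_spec(64))
  fl <- run_federated(ds, spec,
                      fl_config(n_clients = 2, samples_per_client = 20,
                                rounds = 0, seed = 31),
                      train_config(seed = 31))
  ref <- build_model(spec$backbone, spec$head, seed = 31)
  expect_identical(steatoq:::nn_weights(fl$model$net),
                   steatoq:::nn_weights(ref$net))
  expect_identical(nrow(fl$history), 0L)
})

test_that("aggregation preserves the weight schema through a round", {
  ds <- synth_dataset(15, side_px = 16, seed = 37)
  spec <- list(backbone = backbone_spec(input_px = 16),
               head = hybrid_head_spec(64, qdi = qdi_config(2, 3)))
  fl <- run_federated(ds, spec,
                      fl_config(n_clients = 2, samples_per_client = 20,
                                rounds = 1, seed = 41),
                      train_config(seed = 41), test = ds)
  ref <- build_model(spec$backbone, spec$head, seed = 41)
  expect_identical(names(steatoq:::nn_weights(fl$model$net)),
                   names(steatoq:::nn_weights(ref$net)))
  expect_identical(nrow(fl$history), 1L)
  expect_true(fl$history$accuracy >= 0 && fl$history$accuracy <= 1)
})

test_that("collaboration beats a single client of the same shard size", {
  # scaled-down counterpart of the multi-hospital experiment: 4 clients
  # with 100 tiles each vs a lone 100-tile client, majority of 3 seeds
  wins <- 0L
  for (seed in 1:3) {
    ds <- synth_dataset(150, side_px = 16, seed = 100 + seed) # 600 tiles
    sp <- holdout_split(ds, 0.8, seed)
    spec <- list(backbone = backbone_spec(input_px = 16),
                 head = classical_head_spec(64))
    tc <- train_config(seed = seed)
    fl <- run_federated(sp$train, spec,
                        fl_config(n_clients = 4, samples_per_client = 100,
                                  rounds = 10, local_epochs = 1,
                                  seed = seed),
                        tc, loss_spec(1), test = sp$test)
    solo <- run_federated(sp$train, spec,
                          fl_config(n_clients = 1, samples_per_client = 100,
                                    rounds = 10, local_epochs = 1,
                                    seed = seed),
                          tc, loss_spec(1), test = sp$test)
    acc_fl <- fl$history$accuracy[nrow(fl$history)]
    acc_solo <- solo$history$accuracy[nrow(solo$history)]
    if (acc_fl >= acc_solo) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("grid experiment tabulates feasible and infeasible cells", {
  ds <- synth_dataset(30, side_px = 16, seed = 43) # 120 tiles
  spec <- list(backbone = backbone_spec(input_px = 16),
               head = classical_head_spec(64))
  grid <- client_grid_experiment(
    ds, clients = c(2L, 50L), samples_per_client = 40L,
    model_spec = spec,
    fl_template = fl_config(rounds = 2, local_epochs = 1),
    train_cfg = train_config(folds = 2, seed = 47))
  expect_identical(nrow(grid), 2L)
  ok <- grid[grid$n_clients == 2L, ]
  expect_true(is.finite(ok$accuracy_mean) && is.finite(ok$accuracy_sd))
  bad <- grid[grid$n_clients == 50L, ] # needs 2000 tiles, pool has ~96
  expect_true(is.na(bad$accuracy_mean))
  expect_identical(bad$n_folds, 0L)
})
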