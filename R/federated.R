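#' Federated learning configuration
#'
#' Defaults follow the simulated hospital scenario: 15 aggregation rounds
#' with a single local epoch per round, vanilla federated averaging, all
#' clients participating in every round.
#'
#' @param n_clients Number of clients (hospitals); 4, 8, 16 and 32 are the
#'   typical grid values.
#' @param samples_per_client Samples held by each client (50-1000 typical).
#' @param rounds Server aggregation rounds (default 15).
#' @param local_epochs Local epochs per round (default 1).
#' @param seed Integer seed for partitioning and training.
#' @return An `fl_config` object.
#' @export
fl_config <- function(n_clients = 4L, samples_per_client = 250L,
                      rounds = 15L, local_epochs = 1L, seed = 1L) {
  n_clients <- as.integer(n_clients)
  rounds <- as.integer(rounds)
  local_epochs <- as.integer(local_epochs)
  if (n_clients < 1L) stop("n_clients must be >= 1")
  if (rounds < 0L) stop("rounds must be >= 0")
  if (local_epochs < 1L) stop("local_epochs must be >= 1")
  structure(list(n_clients = n_clients,
                 samples_per_client = as.integer(samples_per_client),
                 rounds = rounds, local_epochs = local_epochs,
                 seed = as.integer(seed),
                 aggregation = "size-weighted-mean"),
            class = "fl_config")
}

#' Partition a dataset into disjoint balanced client shards
#'
#' Every client receives exactly `samples_per_client` tiles, equally
#' divided between the two suitability classes, and no tile is assigned to
#' two clients. When a `patient_id` column is present and a patient-level
#' round-robin deal can satisfy the balance constraints, shards are also
#' patient-disjoint; otherwise the partition falls back to tile-level
#' stratified dealing with a message.
#'
#' @param labels Vector of binary labels (1/2 or suitable/not_suitable),
#'   or a manifest data frame with a `label` column.
#' @param config An [fl_config()].
#' @return A list of integer index vectors (sorted), one per client, with
#'   class `client_partition`.
#' @export
partition_dataset <- function(labels, config) {
  stopifnot(inherits(config, "fl_config"))
  patient <- NULL
  if (is.data.frame(labels)) {
    patient <- labels$patient_id
    labels <- labels$label
  }
  y <- class_index(labels)
  # per-client class quotas: exactly balanced for even shard sizes; for odd
  # sizes the extra tile alternates between the classes across clients
  spc <- config$samples_per_client
  quota <- matrix(spc %/% 2L, config$n_clients, 2L)
  if (spc %% 2L == 1L) {
    for (k in seq_len(config$n_clients)) {
      quota[k, 2L - k %% 2L] <- quota[k, 2L - k %% 2L] + 1L
    }
  }
  for (cls in 1:2) {
    need <- sum(quota[, cls])
    have <- sum(y == cls)
    if (have < need) {
      stop("insufficient samples: need ", need, " of class ",
           class_label(cls), ", have ", have)
    }
  }
  shards <- NULL
  if (!is.null(patient)) {
    shards <- partition_by_patient(y, patient, config, quota)
    if (is.null(shards)) {
      message("patient-disjoint partition infeasible; ",
              "falling back to tile-level stratified shards")
    }
  }
  if (is.null(shards)) {
    set.seed(config$seed)
    shards <- replicate(config$n_clients, integer(0), simplify = FALSE)
    for (cls in 1:2) {
      ids <- sample(which(y == cls))
      used <- 0L
      for (k in seq_len(config$n_clients)) {
        take <- ids[used + seq_len(quota[k, cls])]
        used <- used + quota[k, cls]
        shards[[k]] <- c(shards[[k]], take)
      }
    }
  }
  shards <- lapply(shards, sort)
  names(shards) <- sprintf("client_%02d", seq_along(shards))
  structure(shards, class = "client_partition")
}

# deal whole patients round-robin, then draw each shard's per-class quota
# from its patient pool; NULL when any client's pool cannot fill the quota
partition_by_patient <- function(y, patient, config, quota) {
  set.seed(config$seed)
  pats <- sample(unique(patient))
  owner <- rep_len(seq_len(config$n_clients), length(pats))
  shards <- vector("list", config$n_clients)
  for (k in seq_len(config$n_clients)) {
    pool <- which(patient %in% pats[owner == k])
    shard <- integer(0)
    for (cls in 1:2) {
      ids <- pool[y[pool] == cls]
      if (length(ids) < quota[k, cls]) {
        return(NULL)
      }
      shard <- c(shard, ids[sample.int(length(ids), quota[k, cls])])
    }
    shards[[k]] <- shard
  }
  shards
}

#' Vanilla federated averaging of model weights
#'
#' Per-tensor average weighted by each client's sample count; with equal
#' counts this is the plain arithmetic mean. All weight sets must share
#' the same tensor names and shapes.
#'
#' @param weights_list List of weight sets (named lists of numeric
#'   tensors, as returned by the training API).
#' @param sample_counts Integer vector of per-client sample counts
#'   (default: equal weighting).
#' @return A weight set of the same schema.
#' @export
fedavg_aggregate <- function(weights_list,
                             sample_counts = rep(1L, length(weights_list))) {
  if (length(weights_list) == 0L) stop("need at least one client")
  if (length(sample_counts) != length(weights_list)) {
    stop("sample_counts must match the number of clients")
  }
  schema <- names(weights_list[[1]])
  for (w in weights_list[-1]) {
    if (!identical(names(w), schema)) {
      stop("weight schema mismatch across clients")
    }
    for (nm in schema) {
      if (length(w[[nm]]) != length(weights_list[[1]][[nm]])) {
        stop("weight shape mismatch for tensor ", nm)
      }
    }
  }
  wts <- sample_counts / sum(sample_counts)
  out <- weights_list[[1]]
  for (nm in schema) {
    acc <- weights_list[[1]][[nm]] * wts[1]
    for (k in seq_along(weights_list)[-1]) {
      acc <- acc + weights_list[[k]][[nm]] * wts[k]
    }
    out[[nm]] <- acc
  }
  out
}

#' Simulate horizontal federated training
#'
#' Sequential in-process simulation of the hospital scenario: the global
#' model is broadcast, every client trains `local_epochs` epochs on its own
#' shard (Adam state is reset each round; only weights cross the client
#' boundary), the server aggregates with vanilla FedAvg, and the global
#' model is evaluated on a held-out centralized test set.
#'
#' With one client and `rounds = 1`, `local_epochs = E`, the run is
#' bit-identical to centralized training for E epochs (shared epoch-seed
#' stream, shard indices in dataset order).
#'
#' @param dataset Training [tile_dataset()] (already excluding any test
#'   split).
#' @param model_spec Backbone + head specs as in [train_model()]; the
#'   classical head is the reference choice for federated runs.
#' @param config An [fl_config()].
#' @param train_cfg A [train_config()] providing optimizer settings.
#' @param loss A [loss_spec()].
#' @param test Optional held-out [tile_dataset()] evaluated after every
#'   round.
#' @return List with the final global `model`, the `partition`, and a
#'   per-round `history` data frame (round, accuracy, fn_rate on the test
#'   set when given).
#' @export
run_federated <- function(dataset, model_spec, config = fl_config(),
                          train_cfg = train_config(), loss = loss_spec(),
                          test = NULL) {
  stopifnot(inherits(dataset, "tile_dataset"))
  part <- partition_dataset(
    if (!is.null(dataset$meta) && "label" %in% names(dataset$meta)) {
      dataset$meta
    } else {
      dataset$labels
    },
    config)
  shards <- lapply(part, function(idx) dataset_subset(dataset, idx))
  cfg <- train_cfg
  cfg$seed <- config$seed
  global <- build_model(model_spec$backbone, model_spec$head,
                        seed = config$seed)
  history <- vector("list", config$rounds)
  for (rd in seq_len(config$rounds)) {
    client_weights <- vector("list", config$n_clients)
    offset <- (rd - 1L) * config$local_epochs
    for (k in seq_len(config$n_clients)) {
      local <- global
      local$net <- nn_set_weights(local$net, nn_weights(global$net))
      opt <- adam_init(local$net) # moments reset each round
      tr <- train_epochs(local, opt, shards[[k]], config$local_epochs,
                         cfg, loss, epoch_offset = offset)
      client_weights[[k]] <- nn_weights(tr$model$net)
    }
    agg <- fedavg_aggregate(client_weights,
                            vapply(shards, function(s) length(s$labels),
                                   integer(1)))
    global$net <- nn_set_weights(global$net, agg)
    history[[rd]] <- if (!is.null(test)) {
      ev <- evaluate(global, test)
      data.frame(round = rd, accuracy = ev$accuracy, fn_rate = ev$fn_rate)
    } else {
      data.frame(round = rd, accuracy = NA_real_, fn_rate = NA_real_)
    }
  }
  list(model = global, partition = part,
       history = if (config$rounds > 0L) {
         do.call(rbind, history)
       } else {
         data.frame(round = integer(0), accuracy = numeric(0),
                    fn_rate = numeric(0))
       })
}

#' Client-count / shard-size grid experiment
#'
#' Runs k-fold cross-validated federated training over a grid of
#' (samples_per_client, n_clients) cells and tabulates mean and standard
#' deviation of the final-round accuracy, the layout used to compare
#' federated architectures. Cells whose sample demand exceeds the dataset
#' are reported as `NA` (absent), not zero.
#'
#' @param dataset Pool [tile_dataset()].
#' @param clients Integer vector of client counts.
#' @param samples_per_client Integer vector of per-client sample budgets.
#' @param model_spec Backbone + head specs.
#' @param fl_template An [fl_config()] supplying rounds/local_epochs.
#' @param train_cfg A [train_config()]; its `folds` and `split_ratio`
#'   drive the cross-validation.
#' @param loss A [loss_spec()].
#' @param out_csv Optional CSV path.
#' @return Data frame with columns samples_per_client, n_clients,
#'   accuracy_mean, accuracy_sd, n_folds.
#' @export
client_grid_experiment <- function(dataset, clients, samples_per_client,
                                   model_spec = default_model_spec(dataset),
                                   fl_template = fl_config(),
                                   train_cfg = train_config(),
                                   loss = loss_spec(), out_csv = NULL) {
  rows <- list()
  for (spc in samples_per_client) {
    for (ncl in clients) {
      accs <- rep(NA_real_, train_cfg$folds)
      feasible <- TRUE
      for (f in seq_len(train_cfg$folds)) {
        fold_seed <- epoch_seed(train_cfg$seed, 500L + f)
        sp <- holdout_split(dataset, train_cfg$split_ratio, fold_seed)
        flc <- fl_template
        flc$n_clients <- as.integer(ncl)
        flc$samples_per_client <- as.integer(spc)
        flc$seed <- fold_seed
        res <- tryCatch(
          run_federated(sp$train, model_spec, flc, train_cfg, loss,
                        test = sp$test),
          error = function(e) e)
        if (inherits(res, "error")) {
          feasible <- FALSE
          break
        }
        accs[f] <- res$history$accuracy[nrow(res$history)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        samples_per_client = spc, n_clients = ncl,
        accuracy_mean = if (feasible) mean(accs) else NA_real_,
        accuracy_sd = if (feasible) stats::sd(accs) else NA_real_,
        n_folds = if (feasible) train_cfg$folds else 0L)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
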