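#' Backbone, head and model construction
#'
#' Two backbones are specified. `"tiny-test-cnn"` is a small, randomly
#' initialized three-conv-block network that trains on a single CPU in
#' minutes and is the default everywhere in this package (the test suite
#' must run offline). `"pretrained-resnet18"` describes the 1000-feature
#' ImageNet backbone of the original architecture; it can be used for
#' parameter accounting but cannot be built here because pretrained weights
#' are not available offline.
#'
#' @param kind `"tiny-test-cnn"` or `"pretrained-resnet18"`.
#' @param output_dim Backbone feature dimension (1000 for resnet18,
#'   configurable for the tiny backbone).
#' @param input_px Input image side in pixels (tiny backbone; images are
#'   square RGB).
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(kind = c("tiny-test-cnn", "pretrained-resnet18"),
                          output_dim = NULL, input_px = 32L) {
  kind <- match.arg(kind)
  if (is.null(output_dim)) {
    output_dim <- if (kind == "pretrained-resnet18") 1000L else 64L
  }
  output_dim <- as.integer(output_dim)
  if (output_dim <= 0L) stop("output_dim must be positive")
  structure(list(kind = kind, output_dim = output_dim,
                 input_px = as.integer(input_px)),
            class = "backbone_spec")
}

#' @rdname backbone_spec
#' @param backbone_dim Feature dimension delivered by the backbone.
#' @param fc_pre Integer vector of affine layer widths mapping
#'   `backbone_dim` down to the quantum layer's feature capacity; the last
#'   entry must equal `qdi_feature_capacity(qdi)`. One entry means a single
#'   affine layer; two entries insert a tanh nonlinearity between them.
#' @param qdi A [qdi_config()].
#' @param n_classes Number of output classes (2: suitable / not-suitable).
#' @export
hybrid_head_spec <- function(backbone_dim = 1000L, fc_pre = NULL,
                             qdi = qdi_config(), n_classes = 2L) {
  cap <- qdi_feature_capacity(qdi)
  if (is.null(fc_pre)) {
    fc_pre <- if (backbone_dim > 256L) c(512L, cap) else cap
  }
  fc_pre <- as.integer(fc_pre)
  if (fc_pre[length(fc_pre)] != cap) {
    stop("last fc_pre width must equal the QDI feature capacity (", cap, ")")
  }
  structure(list(kind = "hybrid", backbone_dim = as.integer(backbone_dim),
                 fc_pre = fc_pre, qdi = qdi,
                 n_classes = as.integer(n_classes)),
            class = "head_spec")
}

#' @rdname backbone_spec
#' @param hidden Integer vector of hidden affine widths for the classical
#'   baseline head (relu between layers).
#' @export
classical_head_spec <- function(backbone_dim = 1000L, hidden = NULL,
                                n_classes = 2L) {
  if (is.null(hidden)) hidden <- if (backbone_dim > 256L) c(512L, 100L) else 100L
  structure(list(kind = "classical", backbone_dim = as.integer(backbone_dim),
                 hidden = as.integer(hidden),
                 n_classes = as.integer(n_classes)),
            class = "head_spec")
}

#' @rdname backbone_spec
#' @param backbone A `backbone_spec`.
#' @param head A `head_spec` from [hybrid_head_spec()] or
#'   [classical_head_spec()].
#' @param seed Integer seed for weight initialization.
#' @return `build_model()`: a `steatoq_model` ready for training.
#' @export
build_model <- function(backbone = backbone_spec(),
                        head = hybrid_head_spec(backbone$output_dim),
                        seed = 1L) {
  stopifnot(inherits(backbone, "backbone_spec"), inherits(head, "head_spec"))
  if (backbone$kind == "pretrained-resnet18") {
    stop("pretrained-resnet18 weights are not available offline; ",
         "use backbone_spec('tiny-test-cnn')")
  }
  if (head$backbone_dim != backbone$output_dim) {
    stop("head backbone_dim (", head$backbone_dim,
         ") must match backbone output_dim (", backbone$output_dim, ")")
  }
  set.seed(as.integer(seed))
  layers <- tiny_cnn_layers(backbone)
  dims <- c(backbone$output_dim,
            if (head$kind == "hybrid") head$fc_pre else head$hidden)
  for (i in seq_len(length(dims) - 1L)) {
    layers <- c(layers, list(layer_dense(dims[i], dims[i + 1L])))
    if (i < length(dims) - 1L) {
      layers <- c(layers, list(if (head$kind == "hybrid") layer_tanh()
                               else layer_relu()))
    }
  }
  if (head$kind == "hybrid") {
    layers <- c(layers, list(layer_tanh_pi(), layer_qdi(head$qdi)),
                list(layer_dense(head$qdi$n_qubits, head$n_classes)))
  } else {
    layers <- c(layers, list(layer_relu()),
                list(layer_dense(dims[length(dims)], head$n_classes)))
  }
  structure(list(net = nn_sequential(layers), backbone = backbone,
                 head = head, seed = as.integer(seed)),
            class = "steatoq_model")
}

# three conv blocks (conv3x3 -> relu -> 2x2 average pool), then a dense
# projection to the backbone feature dimension
tiny_cnn_layers <- function(backbone) {
  px <- backbone$input_px
  chans <- c(3L, 8L, 16L, 16L)
  layers <- list()
  side <- px
  for (i in 1:3) {
    if (side < 5L) break # too small for another valid 3x3 block
    layers <- c(layers, list(layer_conv(chans[i], chans[i + 1L]),
                             layer_relu(), layer_avgpool()))
    side <- (side - 2L) %/% 2L
  }
  n_blocks <- length(layers) / 3L
  flat <- side * side * chans[n_blocks + 1L]
  c(layers, list(layer_flatten(), layer_dense(flat, backbone$output_dim),
                 layer_relu()))
}

#' @export
print.steatoq_model <- function(x, ...) {
  cat("<steatoq_model> ", x$head$kind, " head, backbone ", x$backbone$kind,
      " (", x$backbone$input_px, "px), ", count_parameters(x)$total,
      " trainable parameters\n", sep = "")
  invisible(x)
}

#' Trainable parameter counts per model component
#'
#' Counts exact trainable parameters for a built model or, arithmetically,
#' for a head specification (weights plus biases for affine layers; one
#' angle per rotation gate for the quantum layer, i.e.
#' `(n_reupload_blocks + 1) * n_qubits`).
#'
#' @param x A `steatoq_model`, `head_spec` or `qdi_config`.
#' @param ... Unused.
#' @return A list of per-component counts with a `total`.
#' @examples
#' count_parameters(qdi_config()) # 105 trainable rotation gates
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.qdi_config <- function(x, ...) {
  n <- qdi_n_parameters(x)
  list(qdi = n, total = n)
}

#' @export
count_parameters.head_spec <- function(x, ...) {
  affine <- function(dims) {
    sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
  }
  if (x$kind == "hybrid") {
    fc_pre <- affine(c(x$backbone_dim, x$fc_pre))
    qdi <- qdi_n_parameters(x$qdi)
    fc_post <- affine(c(x$qdi$n_qubits, x$n_classes))
    list(fc_pre = fc_pre, qdi = qdi, fc_post = fc_post,
         total = fc_pre + qdi + fc_post)
  } else {
    n <- affine(c(x$backbone_dim, x$hidden, x$n_classes))
    list(head = n, total = n)
  }
}

#' @export
count_parameters.steatoq_model <- function(x, ...) {
  per_layer <- vapply(x$net$layers, function(ly) {
    sum(vapply(ly$params, length, integer(1)), 0L)
  }, numeric(1))
  types <- vapply(x$net$layers, function(ly) ly$type, character(1))
  qdi_i <- which(types == "qdi")
  head_counts <- count_parameters(x$head)
  n_head_layers <- if (x$head$kind == "hybrid") {
    # dense layers of fc_pre + qdi + fc_post
    length(x$head$fc_pre) + 2L
  } else {
    length(x$head$hidden) + 1L
  }
  dense_i <- which(types %in% c("dense", "conv", "qdi"))
  head_i <- utils::tail(dense_i, n_head_layers)
  backbone <- sum(per_layer) - sum(per_layer[head_i])
  list(backbone = backbone,
       head = sum(per_layer[head_i]),
       qdi = if (length(qdi_i)) sum(per_layer[qdi_i]) else 0L,
       total = sum(per_layer))
}

#' Class probabilities for a batch of tiles
#'
#' @param object A trained or freshly built `steatoq_model`.
#' @param x Image array `(N, px, px, 3)` with values in `[0, 1]`.
#' @param ... Unused.
#' @return Matrix `(N, 2)` of class probabilities (columns: suitable,
#'   not-suitable); rows sum to 1.
#' @export
predict_proba <- function(object, x, ...) {
  stopifnot(inherits(object, "steatoq_model"))
  x <- check_image_batch(x, object$backbone$input_px)
  logits <- nn_forward(object$net, x)$out
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  colnames(p) <- c("suitable", "not_suitable")
  p
}

check_image_batch <- function(x, px) {
  if (length(dim(x)) != 4L) stop("image batch must be a (N, H, W, C) array")
  d <- dim(x)
  if (d[2] != px || d[3] != px || d[4] != 3L) {
    stop("image batch must be (N, ", px, ", ", px, ", 3), got (",
         paste(d, collapse = ", "), ")")
  }
  x
}
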