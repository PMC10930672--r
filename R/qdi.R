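#' Configuration of the quantum depth-infused (QDI) layer
#'
#' The QDI layer is a data re-uploading variational circuit: classical
#' features are interleaved as Z-axis rotations with trainable X-axis
#' rotation layers and CNOT entanglers across the circuit depth, so that
#' `n_qubits * n_reupload_blocks` features fit on `n_qubits` qubits. The
#' default (5 qubits, 20 blocks) encodes 100 features with
#' `(20 + 1) * 5 = 105` trainable rotation gates: one initial variational
#' row plus one row after each re-uploading block.
#'
#' @param n_qubits Number of qubits (default 5).
#' @param n_reupload_blocks Number of feature re-uploading blocks
#'   (default 20).
#' @param entangler Entangling topology within each variational layer:
#'   `"chain"` applies CNOT(q, q+1) for q = 0..n-2; `"ring"` additionally
#'   closes the chain with CNOT(n-1, 0).
#' @return An object of class `qdi_config`.
#' @examples
#' cfg <- qdi_config()
#' qdi_feature_capacity(cfg) # 100
#' qdi_n_parameters(cfg)     # 105
#' @export
qdi_config <- function(n_qubits = 5L, n_reupload_blocks = 20L,
                       entangler = c("chain", "ring")) {
  n_qubits <- as.integer(n_qubits)
  n_reupload_blocks <- as.integer(n_reupload_blocks)
  if (n_qubits < 1L) stop("n_qubits must be >= 1")
  if (n_reupload_blocks < 1L) stop("n_reupload_blocks must be >= 1")
  entangler <- match.arg(entangler)
  structure(list(n_qubits = n_qubits,
                 n_reupload_blocks = n_reupload_blocks,
                 encoding_axis = "Z",
                 variational_axis = "X",
                 entangler = entangler,
                 readout_observable = "Y"),
            class = "qdi_config")
}

#' @export
print.qdi_config <- function(x, ...) {
  cat("<qdi_config> ", x$n_qubits, " qubits x ", x$n_reupload_blocks,
      " re-uploading blocks (", qdi_feature_capacity(x), " features, ",
      qdi_n_parameters(x), " trainable gates, ", x$entangler,
      " entangler)\n", sep = "")
  invisible(x)
}

#' @rdname qdi_config
#' @param config A `qdi_config`.
#' @return `qdi_feature_capacity()`: the number of classical features the
#'   circuit encodes, `n_qubits * n_reupload_blocks`.
#' @export
qdi_feature_capacity <- function(config) {
  stopifnot(inherits(config, "qdi_config"))
  config$n_qubits * config$n_reupload_blocks
}

#' @rdname qdi_config
#' @return `qdi_n_parameters()`: the number of trainable rotation gates,
#'   `(n_reupload_blocks + 1) * n_qubits`.
#' @export
qdi_n_parameters <- function(config) {
  stopifnot(inherits(config, "qdi_config"))
  (config$n_reupload_blocks + 1L) * config$n_qubits
}

#' Trainable parameters of the QDI layer
#'
#' The parameters form a `(n_reupload_blocks + 1) x n_qubits` matrix of
#' rotation angles in radians. Row 1 is the initial variational layer; row
#' `b + 1` follows re-uploading block `b`.
#'
#' @param config A `qdi_config`.
#' @param theta Optional numeric matrix of the required shape; defaults to
#'   small random angles drawn from `N(0, 0.1)` (uses the current RNG
#'   state, so seed beforehand for reproducibility).
#' @return A numeric matrix with class `qdi_parameters`.
#' @export
qdi_parameters <- function(config, theta = NULL) {
  stopifnot(inherits(config, "qdi_config"))
  rows <- config$n_reupload_blocks + 1L
  cols <- config$n_qubits
  if (is.null(theta)) {
    theta <- matrix(stats::rnorm(rows * cols, sd = 0.1), rows, cols)
  }
  theta <- as.matrix(theta)
  if (nrow(theta) != rows || ncol(theta) != cols) {
    stop("theta must be a ", rows, " x ", cols, " matrix")
  }
  storage.mode(theta) <- "double"
  class(theta) <- c("qdi_parameters", class(theta))
  theta
}

check_qdi_features <- function(features, config) {
  features <- as.numeric(features)
  cap <- qdi_feature_capacity(config)
  if (length(features) != cap) {
    stop("feature vector must have length n_qubits * n_reupload_blocks = ",
         cap, ", got ", length(features))
  }
  features
}

#' Forward evaluation of the QDI circuit
#'
#' Starts in the ground state, applies the initial variational row
#' (X-rotations plus entangling CNOTs), then for each re-uploading block
#' encodes the next `n_qubits` features as Z-rotations followed by that
#' block's variational row, and finally applies the readout transform and
#' measures the Pauli-Y expectation on every qubit. Features are consumed
#' in order: features 1..n_qubits on block 1, the next n_qubits on block 2,
#' and so on.
#'
#' @param features Numeric vector of encoded angles (radians), length
#'   `qdi_feature_capacity(config)`.
#' @param params A `qdi_parameters` matrix (or any matrix of matching
#'   shape).
#' @param config A `qdi_config`.
#' @return Numeric vector of `n_qubits` Pauli-Y expectations in `[-1, 1]`.
#' @export
qdi_forward <- function(features, params, config = qdi_config()) {
  features <- check_qdi_features(features, config)
  params <- qdi_parameters(config, unclass(params))
  cpp_qdi_forward(features, unclass(params), config$n_qubits,
                  config$n_reupload_blocks, config$entangler == "ring")
}

#' Parameter-shift gradient of the QDI circuit
#'
#' Every trainable gate is a single-qubit rotation, so the two-point
#' parameter-shift rule `df/dt = (f(t + pi/2) - f(t - pi/2)) / 2` is exact.
#' The same rule yields the gradient with respect to the encoded features
#' (Z-rotations), which is what makes the layer trainable end-to-end inside
#' a classical network without automatic differentiation.
#'
#' @inheritParams qdi_forward
#' @return A list with elements:
#'   \describe{
#'     \item{theta}{array of shape `(n_reupload_blocks + 1, n_qubits,
#'       n_qubits)`: `[b, q, k]` is the derivative of output `k` with
#'       respect to `theta[b, q]`.}
#'     \item{features}{matrix `(capacity, n_qubits)`: derivative of each
#'       output with respect to each input feature.}
#'   }
#' @export
qdi_gradient <- function(features, params, config = qdi_config()) {
  features <- check_qdi_features(features, config)
  params <- qdi_parameters(config, unclass(params))
  jac <- cpp_qdi_jacobians(features, unclass(params), config$n_qubits,
                           config$n_reupload_blocks,
                           config$entangler == "ring")
  rows <- config$n_reupload_blocks + 1L
  list(theta = array(jac$theta, c(rows, config$n_qubits, config$n_qubits)),
       features = jac$features)
}
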