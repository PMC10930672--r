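#' Class-weighted cross-entropy for transplant suitability
#'
#' Binary cross-entropy with a multiplicative penalty `lambda_fn` on the
#' "not suitable" class: `l = -sum_c w_c y_c log(p_c)` with `w_c = lambda`
#' when `c` is not-suitable and 1 otherwise. A false negative in this
#' package is a diseased (not-suitable, grade 2-3) liver predicted
#' suitable; raising `lambda_fn` makes that error costlier during
#' training. With `lambda_fn = 1` the loss reduces exactly to the plain
#' cross-entropy.
#'
#' @param probabilities Numeric vector of predicted class probabilities in
#'   the order (suitable, not-suitable); must sum to 1 within 1e-6.
#'   Probabilities are clamped at 1e-12 before the logarithm.
#' @param true_class The true class: 1 or `"suitable"`, 2 or
#'   `"not_suitable"`.
#' @param lambda_fn Penalty multiplier for the not-suitable class
#'   (>= 1 in the intended use; any positive value is accepted).
#' @return Non-negative scalar loss.
#' @examples
#' weighted_cross_entropy(c(0.5, 0.5), "suitable", 1)      # log(2)
#' weighted_cross_entropy(c(0.5, 0.5), "not_suitable", 3)  # 3 log(2)
#' @export
weighted_cross_entropy <- function(probabilities, true_class, lambda_fn = 1) {
  probabilities <- as.numeric(probabilities)
  if (length(probabilities) != 2L) {
    stop("probabilities must have length 2 (suitable, not-suitable)")
  }
  if (abs(sum(probabilities) - 1) > 1e-6) {
    stop("probabilities must sum to 1 within 1e-6")
  }
  cls <- class_index(true_class)
  w <- c(1, lambda_fn)[cls]
  -w * log(max(probabilities[cls], 1e-12))
}

class_index <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    idx <- match(x, c("suitable", "not_suitable"))
    if (anyNA(idx)) stop("labels must be 'suitable' or 'not_suitable'")
    idx
  } else {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L | x > 2L)) {
      stop("class index must be 1 (suitable) or 2 (not_suitable)")
    }
    x
  }
}

class_label <- function(idx) c("suitable", "not_suitable")[idx]

# Batch softmax + weighted cross-entropy on logits.  y is an integer vector
# of class indices (1 = suitable, 2 = not-suitable).  Returns the mean loss,
# the probability matrix and the gradient of the mean loss w.r.t. logits:
# dl/dz_c = w_y (p_c - y_c) / N.
softmax_wce <- function(logits, y, lambda_fn = 1) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  w <- c(1, lambda_fn)[y]
  py <- pmax(p[cbind(seq_len(n), y)], 1e-12)
  loss <- mean(-w * log(py))
  onehot <- matrix(0, n, ncol(logits))
  onehot[cbind(seq_len(n), y)] <- 1
  grad <- (p - onehot) * (w / n)
  list(loss = loss, probs = p, grad = grad)
}
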