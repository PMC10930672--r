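# Minimal neural-network stack: just the layer types the steatosis models
# need (valid conv, 2x2 average pooling, dense, relu, pi*tanh squash, and the
# quantum depth-infused layer), with hand-written reverse passes and Adam.
# Images are (N, H, W, C) arrays; dense activations are (N, D) matrices.
# Initialization draws from the current RNG state so callers control seeds.

layer_dense <- function(in_dim, out_dim) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = matrix(stats::rnorm(in_dim * out_dim,
                                             sd = sqrt(2 / in_dim)),
                                in_dim, out_dim),
                     b = numeric(out_dim)))
}

layer_conv <- function(in_c, out_c, k = 3L) {
  list(type = "conv", k = k, in_c = in_c, out_c = out_c,
       params = list(W = array(stats::rnorm(k * k * in_c * out_c,
                                            sd = sqrt(2 / (k * k * in_c))),
                               c(k, k, in_c, out_c)),
                     b = numeric(out_c)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_tanh <- function() list(type = "tanh", params = list())

layer_avgpool <- function() list(type = "avgpool", params = list())

layer_flatten <- function() list(type = "flatten", params = list())

# squashes pre-encoding features into (-pi, pi) so the angle embedding of
# the quantum layer cannot alias
layer_tanh_pi <- function() list(type = "tanh_pi", params = list())

layer_qdi <- function(config) {
  list(type = "qdi", config = config,
       params = list(theta = unclass(qdi_parameters(config))))
}

nn_sequential <- function(layers) structure(list(layers = layers),
                                            class = "nn_sequential")

conv_fwd <- function(x, W, b) {
  d <- dim(x)
  N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  k <- dim(W)[1]; nf <- dim(W)[4]
  oh <- H - k + 1; ow <- Wd - k + 1
  out <- matrix(rep(b, each = N * oh * ow), N * oh * ow, nf)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      xs <- x[, di:(di + oh - 1), dj:(dj + ow - 1), , drop = FALSE]
      out <- out + matrix(xs, nrow = N * oh * ow) %*%
        matrix(W[di, dj, , ], nrow = C)
    }
  }
  array(out, c(N, oh, ow, nf))
}

conv_bwd <- function(x, W, g) {
  d <- dim(x)
  N <- d[1]; C <- d[4]
  k <- dim(W)[1]; nf <- dim(W)[4]
  og <- dim(g)
  oh <- og[2]; ow <- og[3]
  gm <- matrix(g, nrow = N * oh * ow)
  dW <- array(0, dim(W))
  dx <- array(0, d)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      xs <- x[, di:(di + oh - 1), dj:(dj + ow - 1), , drop = FALSE]
      dW[di, dj, , ] <- crossprod(matrix(xs, nrow = N * oh * ow), gm)
      dx[, di:(di + oh - 1), dj:(dj + ow - 1), ] <-
        dx[, di:(di + oh - 1), dj:(dj + ow - 1), , drop = FALSE] +
        array(tcrossprod(gm, matrix(W[di, dj, , ], nrow = C)),
              c(N, oh, ow, C))
    }
  }
  list(dx = dx, grads = list(W = dW, b = colSums(gm)))
}

pool_fwd <- function(x) {
  d <- dim(x)
  oh <- d[2] %/% 2L; ow <- d[3] %/% 2L
  i1 <- seq(1L, 2L * oh, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * ow, 2L); j2 <- j1 + 1L
  (x[, i1, j1, , drop = FALSE] + x[, i2, j1, , drop = FALSE] +
     x[, i1, j2, , drop = FALSE] + x[, i2, j2, , drop = FALSE]) / 4
}

pool_bwd <- function(x, g) {
  d <- dim(x)
  og <- dim(g)
  oh <- og[2]; ow <- og[3]
  i1 <- seq(1L, 2L * oh, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * ow, 2L); j2 <- j1 + 1L
  dx <- array(0, d)
  q <- g / 4
  dx[, i1, j1, ] <- q
  dx[, i2, j1, ] <- q
  dx[, i1, j2, ] <- q
  dx[, i2, j2, ] <- q
  dx
}

nn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    caches[[i]] <- switch(ly$type,
      dense = list(x = x),
      conv = list(x = x),
      relu = list(x = x),
      avgpool = list(x = x),
      flatten = list(dims = dim(x)),
      tanh = NULL,
      tanh_pi = NULL,
      qdi = list(x = x)
    )
    x <- switch(ly$type,
      dense = sweep(x %*% ly$params$W, 2, ly$params$b, "+"),
      conv = conv_fwd(x, ly$params$W, ly$params$b),
      relu = pmax(x, 0),
      avgpool = pool_fwd(x),
      flatten = matrix(x, nrow = dim(x)[1]),
      tanh = tanh(x),
      tanh_pi = pi * tanh(x),
      qdi = cpp_qdi_forward_batch(x, ly$params$theta,
                                  ly$config$n_qubits,
                                  ly$config$n_reupload_blocks,
                                  ly$config$entangler == "ring")
    )
    if (ly$type == "tanh_pi") caches[[i]] <- list(t = x / pi)
    if (ly$type == "tanh") caches[[i]] <- list(t = x)
  }
  list(out = x, caches = caches)
}

nn_backward <- function(model, caches, g) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "dense") {
      grads[[i]] <- list(W = crossprod(cc$x, g), b = colSums(g))
      g <- tcrossprod(g, ly$params$W)
    } else if (ly$type == "conv") {
      r <- conv_bwd(cc$x, ly$params$W, g)
      grads[[i]] <- r$grads
      g <- r$dx
    } else if (ly$type == "relu") {
      g <- g * (cc$x > 0)
    } else if (ly$type == "avgpool") {
      g <- pool_bwd(cc$x, g)
    } else if (ly$type == "flatten") {
      g <- array(g, cc$dims)
    } else if (ly$type == "tanh") {
      g <- g * (1 - cc$t^2)
    } else if (ly$type == "tanh_pi") {
      g <- g * pi * (1 - cc$t^2)
    } else if (ly$type == "qdi") {
      r <- cpp_qdi_backward_batch(cc$x, ly$params$theta, g,
                                  ly$config$n_qubits,
                                  ly$config$n_reupload_blocks,
                                  ly$config$entangler == "ring")
      grads[[i]] <- list(theta = r$theta)
      g <- r$features
    }
    if (is.null(grads[[i]])) grads[[i]] <- list()
  }
  list(grads = grads, grad_in = g)
}

nn_n_params <- function(model) {
  sum(vapply(model$layers,
             function(ly) sum(vapply(ly$params, length, integer(1)), 0L),
             numeric(1)))
}

# Flat named list of parameter tensors, e.g. "layer3.W", "qdi.theta".
nn_weights <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    for (nm in names(ly$params)) {
      key <- if (ly$type == "qdi") "qdi.theta" else paste0("layer", i, ".", nm)
      out[[key]] <- ly$params[[nm]]
    }
  }
  out
}

nn_set_weights <- function(model, weights) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    for (nm in names(ly$params)) {
      key <- if (ly$type == "qdi") "qdi.theta" else paste0("layer", i, ".", nm)
      w <- weights[[key]]
      if (is.null(w)) stop("missing weight tensor: ", key)
      tgt <- ly$params[[nm]]
      if (length(w) != length(tgt)) {
        stop("shape mismatch for weight tensor: ", key)
      }
      model$layers[[i]]$params[[nm]] <-
        if (is.null(dim(tgt))) as.numeric(w) else array(as.numeric(w), dim(tgt))
    }
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_init <- function(model) {
  list(t = 0L,
       m = lapply(model$layers, function(ly) lapply(ly$params, function(p) p * 0)),
       v = lapply(model$layers, function(ly) lapply(ly$params, function(p) p * 0)))
}

adam_step <- function(model, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      model$layers[[i]]$params[[nm]] <- model$layers[[i]]$params[[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) /
          (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(model = model, state = state)
}
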