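# Minimal dense-network machinery: fully connected blocks (dense + batch
# normalization + ReLU + dropout), softmax/linear heads, hand-derived
# backpropagation, and the Adam optimizer. Batches are row-major
# (samples x features) and all heavy products go through BLAS.

nn_dense <- function(n_in, n_out, init_sd = sqrt(2 / n_in)) {
  list(type = "dense",
       W = matrix(stats::rnorm(n_in * n_out, sd = init_sd), n_in, n_out),
       b = rep(0, n_out))
}

nn_bn <- function(n, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, n), beta = rep(0, n),
       run_mean = rep(0, n), run_var = rep(1, n),
       momentum = momentum, eps = eps)
}

nn_relu <- function() list(type = "relu")
nn_sigmoid <- function() list(type = "sigmoid")
nn_dropout <- function(rate) list(type = "dropout", rate = rate)

# A standard fully connected block as used by every channel: FC -> BN ->
# ReLU -> dropout.
nn_fc_block <- function(n_in, n_out, dropout_rate = 0.2) {
  list(nn_dense(n_in, n_out), nn_bn(n_out), nn_relu(), nn_dropout(dropout_rate))
}

# forward_stack: returns list(out, caches, stack) - stack returned because
# BN running statistics are updated in training mode.
forward_stack <- function(stack, X, training = FALSE) {
  caches <- vector("list", length(stack))
  for (i in seq_along(stack)) {
    layer <- stack[[i]]
    if (layer$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- sweep(X %*% layer$W, 2, layer$b, "+")
    } else if (layer$type == "bn") {
      if (training) {
        mu <- colMeans(X)
        va <- colMeans(sweep(X, 2, mu, "-")^2)   # biased, as in the BN forward pass
        stack[[i]]$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
        n <- nrow(X)
        unb <- if (n > 1) va * n / (n - 1) else va
        stack[[i]]$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * unb
      } else {
        mu <- layer$run_mean
        va <- layer$run_var
      }
      inv_sd <- 1 / sqrt(va + layer$eps)
      xhat <- sweep(sweep(X, 2, mu, "-"), 2, inv_sd, "*")
      caches[[i]] <- list(xhat = xhat, inv_sd = inv_sd, training = training)
      X <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
    } else if (layer$type == "relu") {
      caches[[i]] <- list(mask = X > 0)
      X <- X * caches[[i]]$mask
    } else if (layer$type == "sigmoid") {
      X <- 1 / (1 + exp(-X))
      caches[[i]] <- list(out = X)
    } else if (layer$type == "dropout") {
      if (training && layer$rate > 0) {
        keep <- matrix(stats::runif(length(X)) >= layer$rate, nrow(X), ncol(X))
        scale <- 1 / (1 - layer$rate)
        caches[[i]] <- list(mask = keep, scale = scale)
        X <- X * keep * scale
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else stop("unknown layer type ", layer$type)
  }
  list(out = X, caches = caches, stack = stack)
}

# backward_stack: dOut is gradient at the stack output; returns list(dX,
# grads) with grads parallel to the stack (NULL for parameter-free layers).
backward_stack <- function(stack, caches, dOut) {
  grads <- vector("list", length(stack))
  for (i in rev(seq_along(stack))) {
    layer <- stack[[i]]
    cache <- caches[[i]]
    if (layer$type == "dense") {
      grads[[i]] <- list(W = crossprod(cache$X, dOut), b = colSums(dOut))
      dOut <- tcrossprod(dOut, layer$W)
    } else if (layer$type == "bn") {
      xhat <- cache$xhat
      dgamma <- colSums(dOut * xhat)
      dbeta <- colSums(dOut)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dxhat <- sweep(dOut, 2, layer$gamma, "*")
      if (cache$training) {
        n <- nrow(xhat)
        dOut <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(xhat), byrow = TRUE) -
                        xhat * matrix(colMeans(dxhat * xhat), n, ncol(xhat), byrow = TRUE),
                      2, cache$inv_sd, "*")
      } else {
        dOut <- sweep(dxhat, 2, cache$inv_sd, "*")
      }
    } else if (layer$type == "relu") {
      dOut <- dOut * cache$mask
    } else if (layer$type == "sigmoid") {
      dOut <- dOut * cache$out * (1 - cache$out)
    } else if (layer$type == "dropout") {
      if (!is.null(cache$mask)) dOut <- dOut * cache$mask * cache$scale
    }
  }
  list(dX = dOut, grads = grads)
}

# ---- parameter bookkeeping -------------------------------------------------

.TRAINABLE <- list(dense = c("W", "b"), bn = c("gamma", "beta"))

stack_params <- function(stack) {
  lapply(stack, function(l) {
    nms <- .TRAINABLE[[l$type]]
    if (is.null(nms)) NULL else l[nms]
  })
}

stack_set_params <- function(stack, params) {
  for (i in seq_along(stack)) {
    if (!is.null(params[[i]])) for (nm in names(params[[i]])) {
      stack[[i]][[nm]] <- params[[i]][[nm]]
    }
  }
  stack
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else if (is.null(x)) NULL else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.null(p)) return(list(p = NULL, m = m, v = v))
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[nm] <- list(r$p); out_m[nm] <- list(r$m); out_v[nm] <- list(r$v)
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# softmax over rows
softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
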