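# Two-phase training. Phase 1: unsupervised stacked-sparse-autoencoder (SSAE)
# pretraining of the connectome channels' FC blocks on unlabeled extractor
# features. Phase 2: supervised fine-tuning of all trainable layers (the
# extractor stays frozen) with mini-batch Adam, cross-entropy (classification)
# or mean-absolute-error (regression) loss, per-epoch learning-rate decay and
# early stopping on the validation loss.

#' Supervised training configuration
#'
#' Defaults follow the selected hyperparameters: learning rate 0.01, batch
#' size 4, 50 epochs, dropout 0.2 (set on the model), per-epoch learning-rate
#' decrement `learning_rate / epochs`, early stop when the validation loss
#' changes by less than `early_stop_tol` for `early_stop_patience`
#' consecutive epochs.
#' @param learning_rate,batch_size,epochs,early_stop_patience,early_stop_tol,seed
#'   See description.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 4L, epochs = 50L,
                         early_stop_patience = 5L, early_stop_tol = 1e-6,
                         seed = 1L) {
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_tol = early_stop_tol, seed = seed),
            class = "train_config")
}

#' Unsupervised pretraining configuration
#'
#' `learning_rate = NULL` selects the rate from the candidate set
#' `c(0.001, 0.01, 0.1, 0.5)` by validation reconstruction loss.
#' @param learning_rate Fixed rate, or `NULL` to select by validation.
#' @param candidates Candidate learning rates.
#' @param batch_size,epochs Optimization settings (50 epochs).
#' @param sparsity_weight Weight of the sparsity penalty on hidden
#'   activations (default 1e-4).
#' @param sparsity_type `"l1"` (default) or `"kl"` (KL divergence to a target
#'   mean activation `kl_rho`).
#' @param kl_rho Target mean activation for the KL penalty.
#' @param seed RNG seed.
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(learning_rate = 0.01,
                            candidates = c(0.001, 0.01, 0.1, 0.5),
                            batch_size = 4L, epochs = 50L,
                            sparsity_weight = 1e-4,
                            sparsity_type = c("l1", "kl"), kl_rho = 0.05,
                            seed = 1L) {
  structure(list(learning_rate = learning_rate, candidates = candidates,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 sparsity_weight = sparsity_weight,
                 sparsity_type = match.arg(sparsity_type), kl_rho = kl_rho,
                 seed = seed),
            class = "pretrain_config")
}

# one sparse autoencoder: encoder dense(d -> h) + ReLU, decoder dense(h -> d)
# + sigmoid, MSE reconstruction + sparsity penalty, mini-batch Adam.
.train_sae <- function(X, h, cfg, lr) {
  n <- nrow(X); d <- ncol(X)
  enc <- list(nn_dense(d, h), nn_relu())
  dec <- list(nn_dense(h, d, init_sd = sqrt(2 / h)), nn_sigmoid())
  params <- list(enc = stack_params(enc), dec = stack_params(dec))
  state <- adam_init(params)
  losses <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      fe <- forward_stack(enc, xb, training = FALSE)
      fd <- forward_stack(dec, fe$out, training = FALSE)
      err <- fd$out - xb
      m <- length(idx)
      recon <- sum(err^2) / m
      hmean <- fe$out
      if (cfg$sparsity_type == "l1") {
        pen <- cfg$sparsity_weight * sum(abs(hmean)) / m
        dpen <- cfg$sparsity_weight * sign(hmean) / m
      } else {
        rho_hat <- pmin(pmax(colMeans(hmean), 1e-6), 1 - 1e-6)
        rho <- cfg$kl_rho
        pen <- cfg$sparsity_weight *
          sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
        drho <- cfg$sparsity_weight * (-rho / rho_hat + (1 - rho) / (1 - rho_hat))
        dpen <- matrix(drho / m, m, h, byrow = TRUE)
      }
      tot <- tot + (recon + pen) * m
      bd <- backward_stack(dec, fd$caches, 2 * err / m)
      dh <- bd$dX + dpen
      be <- backward_stack(enc, fe$caches, dh)
      step <- adam_step(params, list(enc = be$grads, dec = bd$grads), state, lr)
      params <- step$params; state <- step$state
      enc <- stack_set_params(enc, params$enc)
      dec <- stack_set_params(dec, params$dec)
    }
    losses[epoch] <- tot / n
    if (!is.finite(losses[epoch])) stop("non-finite SSAE loss at epoch ", epoch)
  }
  list(enc = enc, dec = dec, losses = losses)
}

#' Greedy stacked-sparse-autoencoder pretraining of a channel's FC blocks
#'
#' The unlabeled extractor outputs `H(X)` are min-max scaled to `[0, 1]` per
#' dimension (compatible with the sigmoid reconstruction output). Each FC
#' width is pretrained in turn as a sparse autoencoder (ReLU encoder, sigmoid
#' decoder, mean-squared reconstruction error plus sparsity penalty,
#' mini-batch Adam); the codes of one layer, rescaled to `[0, 1]`, feed the
#' next. Returns the encoder (dense) weights for transplant into the fusion
#' model via [transplant_encoder()].
#'
#' @param H Unlabeled feature matrix `n x d` (flattened extractor outputs).
#' @param fc_widths Widths of the FC blocks to pretrain (default `c(64, 16)`).
#' @param cfg A [pretrain_config()].
#' @return List with `encoders` (per layer `list(W, b)`), `history` (loss per
#'   epoch per layer), and `selected_lr`.
#' @export
pretrain_ssae <- function(H, fc_widths = c(64L, 16L), cfg = pretrain_config()) {
  stopifnot(nrow(H) >= 2)
  with_seed(cfg$seed, {
    lr <- cfg$learning_rate
    if (is.null(lr)) {
      lr <- .select_pretrain_lr(H, fc_widths[1], cfg)
      np_log("SSAE learning rate selected by validation: %g", lr)
    }
    X <- minmax_scale(H)
    encoders <- list(); history <- list()
    for (li in seq_along(fc_widths)) {
      fit <- .train_sae(X, fc_widths[li], cfg, lr)
      encoders[[li]] <- list(W = fit$enc[[1]]$W, b = fit$enc[[1]]$b)
      history[[li]] <- fit$losses
      codes <- forward_stack(fit$enc, X, training = FALSE)$out
      X <- minmax_scale(codes)
    }
    list(encoders = encoders, history = history, selected_lr = lr)
  })
}

# validation-based choice from the documented candidate set: short runs on an
# 80/20 split, lowest held-out reconstruction MSE wins.
.select_pretrain_lr <- function(H, h1, cfg) {
  n <- nrow(H)
  idx <- sample.int(n)
  n_val <- max(1L, floor(n / 5))
  val <- idx[seq_len(n_val)]; tr <- idx[-seq_len(n_val)]
  X <- minmax_scale(H[tr, , drop = FALSE])
  Xv <- minmax_scale(H[val, , drop = FALSE],
                     lo = attr(X, "lo"), hi = attr(X, "hi"))
  short <- cfg; short$epochs <- max(5L, cfg$epochs %/% 10L)
  val_loss <- vapply(cfg$candidates, function(lr) {
    fit <- .train_sae(X, h1, short, lr)
    rec <- forward_stack(fit$dec, forward_stack(fit$enc, Xv, FALSE)$out, FALSE)$out
    mean(rowSums((rec - Xv)^2))
  }, numeric(1))
  cfg$candidates[which.min(val_loss)]
}

#' Transplant pretrained encoder weights into a fusion-model channel
#'
#' Writes the pretrained dense weights into the channel's FC blocks (batch
#' norm parameters keep their initialization).
#' @param model A fusion_model.
#' @param channel Channel name (a connectome channel).
#' @param pretrained Result of [pretrain_ssae()].
#' @return The updated model.
#' @export
transplant_encoder <- function(model, channel, pretrained) {
  stopifnot(channel %in% model$channels)
  stack <- model$stacks[[channel]]
  dense_pos <- which(vapply(stack, `[[`, character(1), "type") == "dense")
  stopifnot(length(dense_pos) == length(pretrained$encoders))
  for (i in seq_along(dense_pos)) {
    stopifnot(identical(dim(stack[[dense_pos[i]]]$W), dim(pretrained$encoders[[i]]$W)))
    stack[[dense_pos[i]]]$W <- pretrained$encoders[[i]]$W
    stack[[dense_pos[i]]]$b <- pretrained$encoders[[i]]$b
  }
  model$stacks[[channel]] <- stack
  model
}

# loss + gradient at the head's linear output
.loss_grad <- function(model, fwd, y) {
  n <- length(y)
  if (model$mode == "classify") {
    P <- fwd$out
    Y <- cbind(as.numeric(y == "high"), as.numeric(y == "low"))
    loss <- -sum(Y * log(pmax(P, 1e-12))) / n
    list(loss = loss, d_logits = (P - Y) / n)
  } else {
    pred <- as.numeric(fwd$out)
    err <- pred - (y - model$y_offset)
    list(loss = mean(abs(err)), d_logits = matrix(sign(err) / n, ncol = 1))
  }
}

.eval_loss <- function(model, X, y) {
  fwd <- model_forward(model, X, training = FALSE)
  .loss_grad(model, fwd, y)$loss
}

#' Supervised fine-tuning of a fusion model
#'
#' Optimizes the trainable FC blocks and fusion head (the extractor is not
#' part of the optimization) with mini-batch Adam: cross-entropy loss for
#' classification, mean absolute error for regression. The learning rate is
#' decremented by `learning_rate / epochs` each epoch; training stops early
#' when the validation loss changes by less than the tolerance for
#' `early_stop_patience` consecutive epochs, and the weights achieving the
#' best validation loss are returned. For regression the score mean of the
#' training set is absorbed into an output offset so the linear unit learns
#' deviations around it.
#'
#' @param model A [fusion_model()].
#' @param X Named list of training input matrices (see [model_inputs()]).
#' @param y Training targets: risk classes (`"high"`/`"low"`) for
#'   classification, numeric scores for regression.
#' @param X_val,y_val Validation inputs/targets (real subjects only).
#' @param cfg A [train_config()].
#' @return List with `model` (best-validation weights), `history`
#'   (train/validation loss per epoch), `stopped_epoch`.
#' @export
finetune <- function(model, X, y, X_val, y_val, cfg = train_config()) {
  n <- nrow(X[[model$channels[1]]])
  if (is.null(X_val) || nrow(X_val[[model$channels[1]]]) == 0) {
    stop("validation set must not be empty")
  }
  if (model$mode == "classify") {
    y <- as.character(y); y_val <- as.character(y_val)
    if (length(unique(y)) < 2) stop("single-class training set in classification mode")
    model$y_offset <- 0
  } else {
    model$y_offset <- mean(y)
  }
  hash_before <- if (!is.null(model$extractor)) model$extractor$hash else NULL
  model <- fit_input_scalers(model, X)
  with_seed(cfg$seed, {
    params <- model_params(model)
    state <- adam_init(params)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    best <- list(loss = Inf, params = params, model = model)
    prev_val <- NA_real_; flat_epochs <- 0L; stopped <- cfg$epochs
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate - (epoch - 1) * cfg$learning_rate / cfg$epochs
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- lapply(X, function(m) m[idx, , drop = FALSE])
        fwd <- model_forward(model, Xb, training = TRUE)
        model <- fwd$model
        lg <- .loss_grad(model, fwd, y[idx])
        tot <- tot + lg$loss * length(idx)
        bwd <- model_backward(model, fwd$caches, lg$d_logits)
        step <- adam_step(params, bwd$grads, state, lr)
        params <- step$params; state <- step$state
        model <- model_set_params(model, params)
      }
      val_loss <- .eval_loss(model, X_val, y_val)
      if (!is.finite(val_loss)) stop("non-finite validation loss at epoch ", epoch)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tot / n,
                                     val_loss = val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = params, model = model)
      }
      if (!is.na(prev_val) && abs(val_loss - prev_val) < cfg$early_stop_tol) {
        flat_epochs <- flat_epochs + 1L
        if (flat_epochs >= cfg$early_stop_patience) { stopped <- epoch; break }
      } else flat_epochs <- 0L
      prev_val <- val_loss
    }
    out <- model_set_params(best$model, best$params)
    if (!is.null(hash_before) && !identical(extractor_hash(out$extractor), hash_before)) {
      stop("internal error: extractor weights changed during training")
    }
    list(model = out, history = hist, stopped_epoch = stopped,
         best_val_loss = best$loss)
  })
}

#' Grid search over FC depth and width
#'
#' Exhaustive grid over the number of FC layers (1..4) and a shared neuron
#' count per layer (`2^n, n in 3..6`), evaluated by repeated 2-fold
#' validation; the configuration with the best mean validation loss wins,
#' ties broken toward fewer parameters.
#'
#' @param X Named list of input matrices.
#' @param y Targets.
#' @param mode `"classify"` or `"regress"`.
#' @param depths,widths Grid axes.
#' @param n_rep Number of repeated 2-fold splits.
#' @param cfg A [train_config()] (use few epochs for desk-scale searches).
#' @param seed Seed governing splits and model initialization.
#' @return List with `best_fc_widths`, `results` (per-candidate mean loss).
#' @export
grid_search_architecture <- function(X, y, mode = "classify", depths = 1:4,
                                     widths = c(8L, 16L, 32L, 64L), n_rep = 2L,
                                     cfg = train_config(), seed = 1L) {
  n <- nrow(X[[1]])
  stopifnot(n >= 4)
  input_dims <- lapply(X, ncol)
  grid <- expand.grid(depth = depths, width = widths)
  n_params <- function(d, w) {
    sum(vapply(names(X), function(ch) {
      dims <- c(input_dims[[ch]], rep(w, d))
      sum(dims[-length(dims)] * dims[-1] + dims[-1])
    }, numeric(1))) + length(X) * w * 8
  }
  res <- data.frame(depth = grid$depth, width = grid$width,
                    mean_val_loss = NA_real_)
  for (g in seq_len(nrow(grid))) {
    fcw <- rep(grid$width[g], grid$depth[g])
    losses <- c()
    for (r in seq_len(n_rep)) {
      halves <- with_seed(derive_seed(seed, g, r), {
        idx <- sample.int(n)
        split(idx, rep(1:2, length.out = n))
      })
      for (h in 1:2) {
        tr <- halves[[h]]; te <- halves[[3 - h]]
        if (mode == "classify" && length(unique(y[tr])) < 2) next
        m <- fusion_model(names(X), mode = mode, input_dims = input_dims,
                          fc_widths = fcw, seed = derive_seed(seed, g, r, h))
        fit <- finetune(m, lapply(X, function(z) z[tr, , drop = FALSE]), y[tr],
                        lapply(X, function(z) z[te, , drop = FALSE]), y[te],
                        cfg)
        losses <- c(losses, fit$best_val_loss)
      }
    }
    res$mean_val_loss[g] <- mean(losses)
  }
  ord <- order(res$mean_val_loss,
               mapply(n_params, res$depth, res$width))
  best <- res[ord[1], ]
  list(best_fc_widths = rep(best$width, best$depth), results = res)
}
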