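# The four-channel fusion architecture: fixed convolutional extractors for
# the functional and structural connectome channels, trainable fully
# connected blocks (FC -> batch norm -> ReLU -> dropout) for all four
# channels, and a fusion head (concatenated embeddings -> FC 8 + BN ->
# softmax over 2 classes, or a single linear unit for score regression).

CHANNEL_ORDER <- c("functional", "structural", "dwma", "clinical")

#' Map a connectome matrix to an extractor-ready tensor
#'
#' Functional values are mapped from `[-1, 1]` to `[0, 1]` via `(x + 1) / 2`;
#' structural values are already in `[0, 1]`. The matrix is bilinearly
#' resampled to the extractor's square input size, replicated to 3 channels,
#' and standardized with the fixed constants `(x - 0.5) / 0.25`. The whole
#' mapping is deterministic.
#'
#' @param m A [connectome_matrix()].
#' @param size Target spatial size (extractor input size).
#' @return Array `(size, size, 3)`.
#' @export
prepare_input <- function(m, size = 224L) {
  if (any(!is.finite(m))) stop("non-finite entries in connectome matrix")
  kind <- attr(m, "kind")
  x <- unclass(m)
  if (identical(kind, "functional")) x <- (x + 1) / 2
  x <- bilinear_resize(x, size, size)
  x <- (x - 0.5) / 0.25
  array(rep(x, 3L), c(size, size, 3L))
}

#' Specify one input channel of the fusion model
#'
#' @param name `"functional"`, `"structural"`, `"dwma"` or `"clinical"`.
#' @param input_dim Input dimensionality of the trainable FC stack (for the
#'   connectome channels this is the flattened extractor output length; for
#'   the tabular channels the feature-vector length).
#' @param fc_widths Neuron counts of the FC blocks (default `c(64, 16)`,
#'   matching the selected architecture).
#' @param dropout_rate Dropout probability (default 0.2).
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(name, input_dim, fc_widths = c(64L, 16L),
                         dropout_rate = 0.2) {
  stopifnot(name %in% CHANNEL_ORDER, length(fc_widths) >= 1)
  structure(list(name = name,
                 has_conv_extractor = name %in% c("functional", "structural"),
                 input_dim = as.integer(input_dim),
                 fc_widths = as.integer(fc_widths),
                 dropout_rate = dropout_rate),
            class = "channel_spec")
}

.build_channel_stack <- function(spec) {
  widths <- c(spec$input_dim, spec$fc_widths)
  stack <- list()
  for (i in seq_along(spec$fc_widths)) {
    stack <- c(stack, nn_fc_block(widths[i], widths[i + 1], spec$dropout_rate))
  }
  stack
}

#' Build the fusion model
#'
#' @param channels Character vector of channels to include, in any subset of
#'   `c("functional", "structural", "dwma", "clinical")`. Embeddings are
#'   concatenated in this fixed canonical order.
#' @param mode `"classify"` (softmax over high/low risk) or `"regress"`
#'   (single linear output unit predicting the Bayley-III score).
#' @param extractor Shared fixed extractor for the connectome channels (from
#'   [build_extractor()]); required when a connectome channel is included.
#' @param dwma_dim,clinical_dim Tabular input lengths (11 and 72 by default).
#' @param fc_widths FC widths per channel block (default `c(64, 16)`).
#' @param fusion_width Width of the fusion FC layer (default 8).
#' @param dropout_rate Dropout probability (default 0.2).
#' @param seed Seed for the trainable-weight initialization.
#' @param input_dims Optional named list overriding per-channel input
#'   dimensionalities (used when training on precomputed feature matrices
#'   without carrying the extractor).
#' @return A `fusion_model` object.
#' @export
fusion_model <- function(channels = CHANNEL_ORDER,
                         mode = c("classify", "regress"),
                         extractor = NULL, dwma_dim = 11L, clinical_dim = 72L,
                         fc_widths = c(64L, 16L), fusion_width = 8L,
                         dropout_rate = 0.2, seed = 1L, input_dims = NULL) {
  mode <- match.arg(mode)
  channels <- CHANNEL_ORDER[CHANNEL_ORDER %in% channels]
  stopifnot(length(channels) >= 1)
  needs_ext <- any(channels %in% c("functional", "structural")) &&
    !all(c("functional", "structural")[c("functional", "structural") %in% channels]
         %in% names(input_dims))
  if (needs_ext && is.null(extractor)) {
    stop("a fixed extractor is required for connectome channels")
  }
  flat_len <- if (!is.null(extractor)) extractor_shape(extractor)$flat_length else NA_integer_
  with_seed(seed, {
    specs <- list()
    stacks <- list()
    for (ch in channels) {
      dim_in <- if (!is.null(input_dims[[ch]])) input_dims[[ch]] else
        switch(ch, functional = flat_len, structural = flat_len,
               dwma = dwma_dim, clinical = clinical_dim)
      specs[[ch]] <- channel_spec(ch, dim_in, fc_widths, dropout_rate)
      stacks[[ch]] <- .build_channel_stack(specs[[ch]])
    }
    emb <- utils::tail(fc_widths, 1)
    fusion_in <- emb * length(channels)
    fusion_stack <- c(list(nn_dense(fusion_in, fusion_width),
                           nn_bn(fusion_width), nn_relu()))
    head <- list(nn_dense(fusion_width, if (mode == "classify") 2L else 1L,
                          init_sd = sqrt(1 / fusion_width)))
    structure(list(channels = channels, specs = specs, stacks = stacks,
                   fusion_stack = fusion_stack, head = head, mode = mode,
                   extractor = extractor, embedding_dim = emb,
                   fusion_in = fusion_in, seed = seed),
              class = "fusion_model")
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> mode=%s channels=%s fusion %d -> %d -> %s\n",
              x$mode, paste(x$channels, collapse = "+"), x$fusion_in,
              ncol(x$fusion_stack[[1]]$W),
              if (x$mode == "classify") "softmax(2)" else "linear(1)"))
  if (!is.null(x$extractor)) {
    sh <- extractor_shape(x$extractor)
    cat(sprintf("  extractor: %d conv / %d pool, input %d, flat %d (fixed, %s)\n",
                sh$n_conv, sh$n_pool, x$extractor$input_size, sh$flat_length,
                x$extractor$weight_source))
  }
  invisible(x)
}

# ---- feature precomputation ------------------------------------------------

#' Extract the flattened fixed-extractor features of one connectome
#' @param model A fusion_model (or an extractor).
#' @param m A connectome_matrix.
#' @return Numeric vector of length `flat_length`.
#' @export
connectome_features <- function(model, m) {
  ext <- if (inherits(model, "extractor")) model else model$extractor
  extractor_forward(ext, prepare_input(m, ext$input_size))$flat
}

#' Assemble the per-channel input matrices for a list of records
#'
#' Connectome channels are passed through the fixed extractor (the expensive
#' step — results should be cached by the caller when reused); tabular
#' channels are stacked directly.
#'
#' @param model A fusion_model.
#' @param records List of subject_records (all channels of the model present).
#' @param channels Channels to assemble (default: all model channels).
#' @return Named list of `n x dim` matrices, one per channel.
#' @export
model_inputs <- function(model, records, channels = model$channels) {
  out <- list()
  for (ch in channels) {
    if (ch %in% c("functional", "structural")) {
      out[[ch]] <- t(vapply(records, function(r) {
        v <- r[[ch]]
        if (is.null(v)) stop("record ", r$subject_id, " missing channel '", ch, "'")
        connectome_features(model, v)
      }, numeric(model$specs[[ch]]$input_dim)))
    } else {
      out[[ch]] <- t(vapply(records, function(r) {
        v <- r[[ch]]
        if (is.null(v)) stop("record ", r$subject_id, " missing channel '", ch, "'")
        as.numeric(v)
      }, numeric(model$specs[[ch]]$input_dim)))
    }
  }
  out
}

# ---- model forward / backward ---------------------------------------------

#' Fit per-channel input scaling on training data
#'
#' Tabular channels are z-scored per feature; connectome channels (extractor
#' features) are min-max scaled to `[0, 1]` per feature — the same
#' convention the stacked-sparse-autoencoder pretraining uses, so
#' transplanted encoder weights see identically scaled inputs during
#' fine-tuning. Constants come from the training split only and are stored
#' on the model; every subsequent forward pass applies them (constant
#' features are left unscaled). Fitted automatically by [finetune()].
#' @param model A fusion_model.
#' @param X Named list of training input matrices.
#' @return The model with scalers attached.
#' @export
fit_input_scalers <- function(model, X) {
  model$scalers <- lapply(stats::setNames(nm = model$channels), function(ch) {
    if (ch %in% c("functional", "structural")) {
      lo <- apply(X[[ch]], 2, min)
      rng <- apply(X[[ch]], 2, max) - lo
      rng[rng < 1e-12 | !is.finite(rng)] <- 1
      list(mu = lo, sd = rng)
    } else {
      # z-score continuous features; leave binary/indicator codes as 0/1,
      # consistent with the clinical encoding convention
      mu <- colMeans(X[[ch]])
      sd <- apply(X[[ch]], 2, stats::sd)
      binary <- apply(X[[ch]], 2, function(v) length(unique(v)) <= 2)
      mu[binary] <- 0
      sd[binary] <- 1
      sd[sd < 1e-12 | !is.finite(sd)] <- 1
      list(mu = mu, sd = sd)
    }
  })
  model
}

.scale_input <- function(model, ch, x) {
  s <- model$scalers[[ch]]
  if (is.null(s)) return(x)
  sweep(sweep(x, 2, s$mu, "-"), 2, s$sd, "/")
}

# X: named list of n x dim matrices (one per channel). Returns output
# (n x 2 probabilities or n x 1 scores), caches, and the (possibly
# BN-updated) model.
model_forward <- function(model, X, training = FALSE) {
  embs <- list(); caches <- list()
  for (ch in model$channels) {
    f <- forward_stack(model$stacks[[ch]], .scale_input(model, ch, X[[ch]]), training)
    model$stacks[[ch]] <- f$stack
    embs[[ch]] <- f$out
    caches[[ch]] <- f$caches
  }
  Z <- do.call(cbind, embs[model$channels])
  ff <- forward_stack(model$fusion_stack, Z, training)
  model$fusion_stack <- ff$stack
  fh <- forward_stack(model$head, ff$out, training)
  model$head <- fh$stack
  logits <- fh$out
  out <- if (model$mode == "classify") softmax(logits) else logits
  list(out = out, logits = logits, model = model,
       caches = list(channels = caches, fusion = ff$caches, head = fh$caches))
}

# d_logits: gradient at the head's linear output. Returns grads mirroring the
# trainable stacks plus the gradient at each channel input.
model_backward <- function(model, caches, d_logits) {
  bh <- backward_stack(model$head, caches$head, d_logits)
  bf <- backward_stack(model$fusion_stack, caches$fusion, bh$dX)
  grads <- list(head = bh$grads, fusion = bf$grads, channels = list())
  dX <- list()
  emb <- model$embedding_dim
  for (i in seq_along(model$channels)) {
    ch <- model$channels[i]
    cols <- ((i - 1) * emb + 1):(i * emb)
    bc <- backward_stack(model$stacks[[ch]], caches$channels[[ch]],
                         bf$dX[, cols, drop = FALSE])
    grads$channels[[ch]] <- bc$grads
    dX[[ch]] <- if (is.null(model$scalers[[ch]])) bc$dX else
      sweep(bc$dX, 2, model$scalers[[ch]]$sd, "/")   # chain rule through scaling
  }
  list(grads = grads, dX = dX)
}

model_params <- function(model) {
  list(head = stack_params(model$head),
       fusion = stack_params(model$fusion_stack),
       channels = lapply(model$stacks, stack_params))
}

model_set_params <- function(model, params) {
  model$head <- stack_set_params(model$head, params$head)
  model$fusion_stack <- stack_set_params(model$fusion_stack, params$fusion)
  for (ch in names(model$stacks)) {
    model$stacks[[ch]] <- stack_set_params(model$stacks[[ch]], params$channels[[ch]])
  }
  model
}

#' Encode one channel of a record to its 16-dimensional embedding
#'
#' Connectome channels run through the fixed extractor, flatten, then the
#' trainable FC blocks; tabular channels go straight into their FC blocks.
#' Evaluation mode (dropout off, BN running statistics), so repeated calls
#' are identical.
#'
#' @param model A fusion_model.
#' @param channel Channel name.
#' @param record A subject_record.
#' @return Numeric embedding vector (length = last FC width, default 16).
#' @export
encode_channel <- function(model, channel, record) {
  stopifnot(channel %in% model$channels)
  X <- model_inputs(model, list(record))[channel]
  as.numeric(forward_stack(model$stacks[[channel]], X[[channel]], FALSE)$out)
}

#' Predict from a single subject record
#'
#' @param model A fusion_model.
#' @param record A subject_record with all the model's channels present.
#' @return For classification, named probabilities `c(high, low)` summing to
#'   1; for regression, a single predicted score.
#' @export
predict_record <- function(model, record) {
  X <- model_inputs(model, list(record))
  out <- model_forward(model, X, training = FALSE)$out
  if (model$mode == "classify") stats::setNames(as.numeric(out), c("high", "low"))
  else as.numeric(out) + .y_offset(model)
}

.y_offset <- function(model) if (is.null(model$y_offset)) 0 else model$y_offset

#' Batch predictions from precomputed channel inputs
#' @param model A fusion_model.
#' @param X Named list of `n x dim` input matrices (see [model_inputs()]).
#' @return `n x 2` probability matrix (classify) or length-n score vector.
#' @export
predict_inputs <- function(model, X) {
  out <- model_forward(model, X, training = FALSE)$out
  if (model$mode == "classify") {
    colnames(out) <- c("high", "low")
    out
  } else as.numeric(out) + .y_offset(model)
}
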