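# Gradient-based identification of discriminative features. Tabular channels
# (DWMA, clinical): partial derivatives of the softmax high-risk output with
# respect to the input features, averaged as mean absolute gradients over
# subjects. Connectome channels: Grad-CAM — gradients at the last
# convolutional layer's feature maps, global-average-pooled into per-map
# weights, combined with ReLU, normalized and rescaled to adjacency-matrix
# size.

# gradient of the target softmax probability at the head's linear output
.softmax_output_grad <- function(P, class_index = 1L) {
  n <- nrow(P); K <- ncol(P)
  onehot <- matrix(0, n, K); onehot[, class_index] <- 1
  P[, class_index] * (onehot - P)
}

#' Rank tabular features by mean absolute partial derivative
#'
#' For each evaluation subject, the gradient of the high-risk softmax output
#' with respect to the channel's input vector is computed (dropout disabled,
#' batch norm in evaluation mode); the importance weight of a feature is the
#' mean absolute gradient across subjects.
#'
#' @param model A trained classification [fusion_model()].
#' @param X Named list of input matrices for the evaluation records (see
#'   [model_inputs()]).
#' @param channel `"dwma"` or `"clinical"`.
#' @param feature_names Optional feature labels.
#' @param class_index Softmax output to differentiate (1 = high risk).
#' @return data.frame `(feature, weight)` sorted by decreasing weight.
#' @export
rank_tabular <- function(model, X, channel = c("clinical", "dwma"),
                         feature_names = NULL, class_index = 1L) {
  channel <- match.arg(channel)
  if (model$mode != "classify") {
    stop("feature ranking is defined on the softmax output: model must be in classify mode")
  }
  stopifnot(channel %in% model$channels)
  fwd <- model_forward(model, X, training = FALSE)
  bwd <- model_backward(model, fwd$caches,
                        .softmax_output_grad(fwd$out, class_index))
  g <- bwd$dX[[channel]]
  w <- colMeans(abs(g))
  if (is.null(feature_names)) {
    feature_names <- colnames(X[[channel]])
    if (is.null(feature_names)) {
      feature_names <- sprintf("%s_%02d", channel, seq_along(w))
    }
  }
  out <- data.frame(feature = feature_names, weight = as.numeric(w))
  out[order(-out$weight), , drop = FALSE]
}

#' Grad-CAM heatmap of a connectome channel for one subject
#'
#' Gradients of the high-risk softmax output are taken at the last
#' convolutional layer's feature maps `A^k`; per-map weights are the global
#' average pool of the gradients, `alpha_k = GAP(ds/dA^k)`; the heatmap is
#' `ReLU(sum_k alpha_k A^k)`, min-max normalized to `[0, 1]`, bilinearly
#' rescaled to the adjacency-matrix size and symmetrized as `(H + H') / 2`
#' (connections are undirected). Normalization is applied after rescaling
#' and symmetrization so a non-zero map attains exactly 1. If the weighted
#' sum is nowhere positive, an all-zero map is returned with a warning.
#'
#' @param model A trained classification [fusion_model()] with an extractor.
#' @param record A [subject_record()].
#' @param channel `"functional"` or `"structural"`.
#' @param class_index Softmax output to differentiate (1 = high risk).
#' @return List with `map` (n x n symmetric heat values in `[0, 1]`),
#'   `alpha` (per-feature-map weights), `channel`.
#' @export
gradcam <- function(model, record, channel = c("functional", "structural"),
                    class_index = 1L) {
  channel <- match.arg(channel)
  if (model$mode != "classify") stop("Grad-CAM is defined on the softmax output")
  stopifnot(channel %in% model$channels, !is.null(model$extractor))
  m <- record[[channel]]
  if (is.null(m)) stop("record ", record$subject_id, " missing channel '", channel, "'")
  n_roi <- nrow(m)
  ext <- model$extractor
  ec <- extractor_forward(ext, prepare_input(m, ext$input_size), keep_cache = TRUE)
  # other channels feed the fusion head as usual (target channel reuses the
  # cached forward pass)
  X <- model_inputs(model, list(record), channels = setdiff(model$channels, channel))
  X[[channel]] <- matrix(ec$flat, nrow = 1)
  X <- X[model$channels]
  fwd <- model_forward(model, X, training = FALSE)
  bwd <- model_backward(model, fwd$caches,
                        .softmax_output_grad(fwd$out, class_index))
  dA <- extractor_backward_to_last_conv(ec, as.numeric(bwd$dX[[channel]]))
  alpha <- apply(dA, 3, mean)                      # GAP of the gradients
  A <- ec$last_conv
  H <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) H <- H + alpha[k] * A[, , k]
  H[H < 0] <- 0                                    # ReLU
  if (max(H) <= 0) {
    warning("Grad-CAM weighted sum nowhere positive: returning all-zero map")
    return(list(map = matrix(0, n_roi, n_roi), alpha = alpha, channel = channel))
  }
  H <- bilinear_resize(H, n_roi, n_roi)
  H <- (H + t(H)) / 2
  H <- (H - min(H)) / (max(H) - min(H))
  list(map = H, alpha = alpha, channel = channel)
}

#' Rank ROI pairs from cohort Grad-CAM maps
#'
#' Averages the heatmaps across subjects, reads the upper triangle and
#' reports the `top_n` strongest region-to-region connections with their ROI
#' names and hemispheric classification.
#'
#' @param maps List of Grad-CAM results (or raw n x n matrices) of one
#'   channel and size.
#' @param labels ROI name vector of length n. Hemisphere is read from a
#'   trailing `L`/`R` token (e.g. `"ROI_12_L"`); if absent, odd indices are
#'   treated as left, even as right (anatomical-atlas numbering convention).
#' @param top_n Number of connections to report.
#' @return data.frame `(roi_a, roi_b, name_a, name_b, weight, hemisphere)`
#'   with hemisphere in `intra-left`, `intra-right`, `interhemispheric`.
#' @export
top_connections <- function(maps, labels, top_n = 10L) {
  mats <- lapply(maps, function(m) if (is.list(m)) m$map else m)
  n <- nrow(mats[[1]])
  stopifnot(all(vapply(mats, nrow, integer(1)) == n))
  if (length(labels) != n) {
    stop("label count ", length(labels), " does not match map size ", n)
  }
  avg <- Reduce(`+`, mats) / length(mats)
  ut <- which(upper.tri(avg), arr.ind = TRUE)
  w <- avg[ut]
  ord <- order(-w)[seq_len(min(top_n, length(w)))]
  hemi <- function(i) {
    lab <- labels[i]
    if (grepl("(^|[._-])L$", lab)) "left"
    else if (grepl("(^|[._-])R$", lab)) "right"
    else if (i %% 2L == 1L) "left" else "right"
  }
  ha <- vapply(ut[ord, 1], hemi, character(1))
  hb <- vapply(ut[ord, 2], hemi, character(1))
  data.frame(
    roi_a = ut[ord, 1], roi_b = ut[ord, 2],
    name_a = labels[ut[ord, 1]], name_b = labels[ut[ord, 2]],
    weight = w[ord],
    hemisphere = ifelse(ha == hb, paste0("intra-", ha), "interhemispheric"))
}
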