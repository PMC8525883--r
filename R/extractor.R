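# Fixed convolutional feature extractor for the connectome channels: 16
# convolutional layers (3x3 kernels, ReLU) interleaved with 5 max-pooling
# layers (2x2, stride 2) in the VGG-19 layout
# (64,64 | 128,128 | 256x4 | 512x4 | 512x4). The weights are frozen during
# every training phase; they come either from a seeded random draw (default,
# self-contained) or from user-supplied pretrained weight files.

#' Channel widths of the 16 convolutional layers (full profile)
#'
#' The canonical VGG-19 convolutional layout: 64,64 | 128,128 | 256 x 4 |
#' 512 x 4 | 512 x 4, with max pooling after layers 2, 4, 8, 12 and 16.
#' @export
VGG_WIDTHS_FULL <- c(64, 64, 128, 128, 256, 256, 256, 256,
                     512, 512, 512, 512, 512, 512, 512, 512)

#' Reduced-width extractor profile for desk-scale experiments
#'
#' Identical 16-conv / 5-pool structure at one eighth the channel widths;
#' used by the simulated-cohort experiments where forward cost matters.
#' @export
VGG_WIDTHS_REDUCED <- VGG_WIDTHS_FULL / 8
# pooling follows conv layers 2, 4, 8, 12, 16
POOL_AFTER <- c(2L, 4L, 8L, 12L, 16L)

#' Build a fixed convolutional extractor
#'
#' @param widths Channel widths of the 16 conv layers
#'   (`VGG_WIDTHS_FULL` or `VGG_WIDTHS_REDUCED`).
#' @param input_size Spatial input size (square); default 224.
#' @param in_channels Input channels (3: the single-channel adjacency image
#'   is replicated).
#' @param weight_source `"seeded-random"` (default; He-scaled Gaussian
#'   filters drawn from `seed`) or `"pretrained"` (weights supplied via
#'   `weights`).
#' @param seed Seed for the random filter draw.
#' @param weights For `weight_source = "pretrained"`: list of per-layer
#'   `list(W, b)` with `W` of shape `(9 * in_ch) x out_ch`.
#' @return An `extractor` object: conv weights, layout, and a SHA-like
#'   content hash used to assert immutability.
#' @export
build_extractor <- function(widths = VGG_WIDTHS_FULL, input_size = 224L,
                            in_channels = 3L,
                            weight_source = c("seeded-random", "pretrained"),
                            seed = 42L, weights = NULL) {
  weight_source <- match.arg(weight_source)
  stopifnot(length(widths) == 16L)
  layers <- vector("list", 16L)
  if (weight_source == "seeded-random") {
    with_seed(seed, {
      cin <- in_channels
      for (i in 1:16) {
        fan_in <- 9 * cin
        layers[[i]] <- list(
          W = matrix(stats::rnorm(widths[i] * fan_in, sd = sqrt(2 / fan_in)),
                     nrow = widths[i], ncol = fan_in),
          b = rep(0, widths[i]))
        cin <- widths[i]
      }
    })
  } else {
    stopifnot(length(weights) == 16L)
    layers <- weights
  }
  ext <- structure(list(layers = layers, widths = widths,
                        input_size = as.integer(input_size),
                        in_channels = as.integer(in_channels),
                        pool_after = POOL_AFTER,
                        weight_source = weight_source, seed = seed),
                   class = "extractor")
  ext$hash <- extractor_hash(ext)
  ext
}

#' Content hash of extractor weights (immutability check)
#' @param ext An extractor.
#' @return Character digest.
#' @export
extractor_hash <- function(ext) {
  v <- unlist(lapply(ext$layers, function(l) c(as.numeric(l$W), l$b)))
  # cheap rolling checksum; enough to detect any weight change
  s1 <- sum(v); s2 <- sum(v * seq_along(v) %% 97)
  sprintf("%.10e|%.10e|%d", s1, s2, length(v))
}

#' Number of conv / pool layers and output shape of an extractor
#'
#' Output spatial size follows five stride-2 halvings (floor) of the input
#' size; the flattened length is `size^2 * last_width`.
#' @param ext An extractor.
#' @return List with `n_conv`, `n_pool`, `out_size`, `out_channels`,
#'   `flat_length`.
#' @export
extractor_shape <- function(ext) {
  s <- ext$input_size
  for (i in seq_along(ext$pool_after)) s <- s %/% 2L
  list(n_conv = length(ext$layers), n_pool = length(ext$pool_after),
       out_size = s, out_channels = ext$widths[16],
       flat_length = s * s * ext$widths[16])
}

# ---- conv / pool primitives ------------------------------------------------

.im2col_env <- new.env(parent = emptyenv())

# gather-index matrix for 3x3 same-padding conv on an (H, W, C) array
.im2col_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "_")
  cached <- .im2col_env[[key]]
  if (!is.null(cached)) return(cached)
  Hp <- H + 2L; Wp <- W + 2L
  offs <- as.vector(outer(0:2, (0:2) * Hp, "+"))          # 3x3 window, col-major
  offs <- as.vector(outer(offs, (seq_len(C) - 1L) * Hp * Wp, "+"))
  starts <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
  idx <- outer(offs, starts, "+")                          # (9C) x (HW)
  storage.mode(idx) <- "integer"
  if (length(idx) <= 2e7) .im2col_env[[key]] <- idx
  idx
}

# x: (H, W, C) array; W_mat: out_ch x (9 in_ch); returns (H, W, out_ch)
conv2d_relu <- function(x, W_mat, b, relu = TRUE) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  idx <- .im2col_idx(d[1], d[2], d[3])
  patches <- matrix(xp[idx], nrow = nrow(idx))
  out <- W_mat %*% patches + b                             # F x HW
  if (relu) out[out < 0] <- 0
  aperm(array(out, c(nrow(W_mat), d[1], d[2])), c(2, 3, 1))
}

# 2x2 stride-2 max pool with argmax cache; odd trailing row/col dropped
maxpool2 <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  i1 <- seq_len(H2) * 2L - 1L; j1 <- seq_len(W2) * 2L - 1L
  a <- x[i1, j1, , drop = FALSE]; b <- x[i1 + 1L, j1, , drop = FALSE]
  cc <- x[i1, j1 + 1L, , drop = FALSE]; dd <- x[i1 + 1L, j1 + 1L, , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  # first-max tie break in the fixed order a, b, c, d (deterministic)
  arg <- array(1L, dim(m))
  arg[m == b & a < m] <- 2L
  arg[m == cc & a < m & b < m] <- 3L
  arg[m == dd & a < m & b < m & cc < m] <- 4L
  list(out = m, arg = arg)
}

# route gradient back through a cached max pool
maxunpool2 <- function(dy, arg, in_dim) {
  dx <- array(0, in_dim)
  d <- dim(dy)
  i1 <- seq_len(d[1]) * 2L - 1L; j1 <- seq_len(d[2]) * 2L - 1L
  for (which in 1:4) {
    sel <- arg == which
    if (!any(sel)) next
    g <- dy * sel
    di <- if (which %in% c(2L, 4L)) 1L else 0L
    dj <- if (which %in% c(3L, 4L)) 1L else 0L
    cur <- dx[i1 + di, j1 + dj, , drop = FALSE]
    dx[i1 + di, j1 + dj, ] <- cur + array(g, dim(cur))
  }
  dx
}

#' Run the fixed extractor forward
#'
#' @param ext An extractor from [build_extractor()].
#' @param x Prepared input array `(input_size, input_size, in_channels)`.
#' @param keep_cache Keep the last conv layer's (post-ReLU) feature maps and
#'   the final pool's argmax — needed for Grad-CAM.
#' @return List with `flat` (flattened output vector, column-major over
#'   `(h, w, channel)`), and when `keep_cache` is set, `last_conv`
#'   (feature maps `A^k`) and `pool_arg`/`pool_in_dim` for unpooling.
#' @export
extractor_forward <- function(ext, x, keep_cache = FALSE) {
  stopifnot(identical(dim(x), c(ext$input_size, ext$input_size, ext$in_channels)))
  if (any(!is.finite(x))) stop("non-finite entries in extractor input")
  last_conv <- NULL; pool_arg <- NULL; pool_in_dim <- NULL
  for (i in 1:16) {
    x <- conv2d_relu(x, ext$layers[[i]]$W, ext$layers[[i]]$b)
    if (i == 16L && keep_cache) last_conv <- x
    if (i %in% ext$pool_after) {
      p <- maxpool2(x)
      if (i == 16L && keep_cache) {
        pool_arg <- p$arg
        pool_in_dim <- dim(x)
      }
      x <- p$out
    }
  }
  out <- list(flat = as.numeric(x), out_dim = dim(x))
  if (keep_cache) {
    out$last_conv <- last_conv
    out$pool_arg <- pool_arg
    out$pool_in_dim <- pool_in_dim
  }
  out
}

# gradient at the last conv feature maps, given gradient at the flattened
# extractor output
extractor_backward_to_last_conv <- function(cache, d_flat) {
  dy <- array(d_flat, cache$out_dim)
  maxunpool2(dy, cache$pool_arg, cache$pool_in_dim)
}
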