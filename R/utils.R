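# Small shared helpers: seeded RNG isolation, bilinear resampling, logging.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream. All stochastic functions in the package route their
#' randomness through this helper.
#'
#' @param seed Integer seed (must be a valid input to [set.seed()]).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a child seed from a base seed and stage indices
#'
#' Keeps derived seeds inside the 32-bit integer range expected by
#' [set.seed()].
#' @keywords internal
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 1e6
  for (i in seq_along(idx)) s <- (s * 31 + as.double(idx[i])) %% 2147483647
  as.integer(s)
}

#' Bilinear resampling of a matrix or multi-channel array
#'
#' Resamples on the half-pixel-centre convention: output pixel centre `i`
#' (1-based) maps to input coordinate `(i - 0.5) * n_in / n_out + 0.5`, so
#' resampling to the input size is exactly the identity. Coordinates beyond
#' the first/last centre are clamped (edge replication).
#'
#' @param x Matrix (`h x w`) or array (`h x w x c`).
#' @param out_h,out_w Output height and width.
#' @return Resampled matrix or array with the same number of channels.
#' @export
bilinear_resize <- function(x, out_h, out_w = out_h) {
  d <- dim(x)
  stopifnot(length(d) %in% c(2L, 3L))
  Ry <- .interp_matrix(d[1], out_h)
  Rx <- .interp_matrix(d[2], out_w)
  if (length(d) == 2L) return(Ry %*% x %*% t(Rx))
  out <- array(0, c(out_h, out_w, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- Ry %*% x[, , k] %*% t(Rx)
  out
}

# n_out x n_in row-interpolation matrix (two non-zeros per row)
.interp_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  src <- pmin(pmax(src, 1), n_in)
  lo <- pmin(floor(src), n_in - 1L)
  w <- src - lo
  R <- matrix(0, n_out, n_in)
  R[cbind(seq_len(n_out), lo)] <- 1 - w
  R[cbind(seq_len(n_out), lo + 1L)] <- R[cbind(seq_len(n_out), lo + 1L)] + w
  R
}

#' Package log messages (stderr, optional logfile)
#' @keywords internal
np_log <- function(..., logfile = getOption("neopredict.logfile", NULL)) {
  msg <- paste0("[neopredict] ", sprintf(...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Min-max scale columns of a matrix to [0, 1]
#'
#' Constant columns map to 0. Returns the scaled matrix with the ranges kept
#' as attributes so new data can be scaled consistently.
#' @keywords internal
minmax_scale <- function(x, lo = NULL, hi = NULL) {
  if (is.null(lo)) lo <- apply(x, 2, min)
  if (is.null(hi)) hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  out <- sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
  out <- pmin(pmax(out, 0), 1)
  attr(out, "lo") <- lo
  attr(out, "hi") <- hi
  out
}

upper_tri_vec <- function(m) m[upper.tri(m)]

vec_to_sym <- function(v, n, diag_value = 0) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}
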