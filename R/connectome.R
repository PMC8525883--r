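# Connectome construction (functional: Pearson correlation of ROI time
# series; structural: mean fractional anisotropy over tracts) and cross-site
# harmonization of feature matrices with ComBat.

#' Functional connectome from an ROI time-series table
#'
#' Entry (i, j) is the Pearson correlation of the BOLD time series of ROIs i
#' and j; the diagonal is 1. Raw correlations are used (no thresholding or
#' Fisher transform).
#'
#' @param ts Numeric `T x n` matrix: `T` frames (rows), `n` ROIs (columns).
#' @param expected_n Node-count override for reduced-size parcellations
#'   (default 223).
#' @return A functional [connectome_matrix()].
#' @export
functional_connectome <- function(ts, expected_n = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 time points, got ", nrow(ts))
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance time series for ROI(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  m <- stats::cor(ts)
  diag(m) <- 1
  m <- (m + t(m)) / 2
  connectome_matrix(m, "functional",
                    expected_n = if (is.null(expected_n)) ncol(ts) else expected_n)
}

#' Structural connectome from a tract table
#'
#' The tract table is long-format: one row per tract voxel with columns
#' `tract_id`, `roi_a`, `roi_b`, `fa`. Per tract, the FA values of its voxels
#' are averaged; the edge between two nodes is the mean of the tract means
#' over all tracts joining them. Node pairs with no tract get 0. Self tracts
#' (`roi_a == roi_b`) are not counted as edges and are dropped with a warning.
#'
#' @param tracts data.frame with columns `tract_id`, `roi_a`, `roi_b`, `fa`
#'   (ROI indices 1-based in `1..n`).
#' @param n Node count (default 90).
#' @return A structural [connectome_matrix()].
#' @export
structural_connectome <- function(tracts, n = 90L) {
  tracts <- as.data.frame(tracts)
  req <- c("tract_id", "roi_a", "roi_b", "fa")
  if (!all(req %in% colnames(tracts))) {
    stop("tract table needs columns: ", paste(req, collapse = ", "))
  }
  m <- matrix(0, n, n)
  if (nrow(tracts) == 0) {
    return(connectome_matrix(m, "structural", expected_n = n))
  }
  if (any(tracts$fa < 0 | tracts$fa > 1)) {
    stop("FA values outside [0,1] in tract table")
  }
  if (any(tracts$roi_a < 1 | tracts$roi_a > n | tracts$roi_b < 1 | tracts$roi_b > n)) {
    stop("ROI indices outside 1..", n)
  }
  self <- tracts$roi_a == tracts$roi_b
  if (any(self)) {
    warning("dropping ", length(unique(tracts$tract_id[self])),
            " self-connecting tract(s)")
    tracts <- tracts[!self, , drop = FALSE]
  }
  if (nrow(tracts)) {
    tract_mean <- tapply(tracts$fa, tracts$tract_id, mean)
    first <- !duplicated(tracts$tract_id)
    a <- pmin(tracts$roi_a[first], tracts$roi_b[first])
    b <- pmax(tracts$roi_a[first], tracts$roi_b[first])
    means <- as.numeric(tract_mean[as.character(tracts$tract_id[first])])
    key <- paste(a, b)
    edge <- tapply(means, key, mean)
    ij <- do.call(rbind, strsplit(names(edge), " "))
    ij <- apply(ij, 2, as.integer)
    if (is.null(dim(ij))) ij <- matrix(ij, nrow = 1)
    m[cbind(ij[, 1], ij[, 2])] <- as.numeric(edge)
    m[cbind(ij[, 2], ij[, 1])] <- as.numeric(edge)
  }
  connectome_matrix(m, "structural", expected_n = n)
}

#' ComBat harmonization of a subjects-by-features matrix
#'
#' Removes additive and multiplicative site/batch effects with the parametric
#' empirical-Bayes location/scale model (ComBat), keeping the matrix
#' dimensions unchanged. Single-batch input passes through unchanged with a
#' warning; features with (near) zero overall variance are skipped with a
#' warning and returned untouched.
#'
#' The estimator standardizes each feature against the batch-size-weighted
#' grand mean and the pooled residual variance, estimates per-batch location
#' (gamma) and scale (delta) parameters, shrinks them with the parametric
#' empirical-Bayes priors (normal for gamma, inverse gamma for delta, moment
#' matched, solved by the standard fixed-point iteration), removes the
#' shrunken effects and restores the grand mean and pooled variance.
#' Location and scale estimates share one variance normalization, so two
#' statistically identical batches pass through bit-near-exactly; when the
#' across-feature variance of an estimate collapses (all features alike) the
#' degenerate prior applies no shrinkage. Agreement with the reference
#' implementation in the sva package is asserted in the test suite.
#'
#' @param x Numeric `subjects x features` matrix.
#' @param batch Batch label per subject (length `nrow(x)`); every batch must
#'   contain at least 2 subjects.
#' @return Harmonized matrix, same dimensions and dimnames as `x`.
#' @export
combat_harmonize <- function(x, batch) {
  x <- as.matrix(x)
  stopifnot(length(batch) == nrow(x))
  batch <- droplevels(as.factor(batch))
  if (nlevels(batch) < 2) {
    warning("single batch: returning input unchanged")
    return(x)
  }
  counts <- table(batch)
  if (any(counts < 2)) {
    stop("each batch needs >= 2 subjects; offending batch(es): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  v <- apply(x, 2, stats::var)
  keep <- which(v > 1e-12)
  if (length(keep) < ncol(x)) {
    warning("skipping ", ncol(x) - length(keep),
            " zero-variance feature(s); returned unharmonized")
  }
  out <- x
  if (length(keep)) {
    out[, keep] <- .combat_eb(x[, keep, drop = FALSE], batch)
  }
  out
}

# parametric EB location/scale batch correction on samples x features data
.combat_eb <- function(x, batch) {
  N <- nrow(x)
  idx <- split(seq_len(N), batch)
  n_b <- vapply(idx, length, numeric(1))
  # batch means, weighted grand mean, pooled residual variance (1/N)
  bhat <- t(vapply(idx, function(ii) colMeans(x[ii, , drop = FALSE]),
                   numeric(ncol(x))))
  grand <- as.numeric(crossprod(n_b / N, bhat))
  resid <- x - bhat[as.integer(batch), , drop = FALSE]
  var_pooled <- colSums(resid^2) / N
  s <- sweep(sweep(x, 2, grand, "-"), 2, sqrt(var_pooled), "/")
  out <- s
  for (b in seq_along(idx)) {
    ii <- idx[[b]]
    sb <- s[ii, , drop = FALSE]
    g_hat <- colMeans(sb)
    d_hat <- colMeans(sweep(sb, 2, g_hat, "-")^2)   # same 1/n normalization
    nb <- n_b[b]
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    g_star <- g_hat; d_star <- d_hat
    if (is.finite(t2) && t2 > 1e-12 && is.finite(s2) && s2 > 1e-12) {
      a_pr <- (2 * s2 + m^2) / s2
      b_pr <- (m * s2 + m^3) / s2
      for (it in 1:200) {
        g_new <- (nb * t2 * g_hat + d_star * g_bar) / (nb * t2 + d_star)
        sse <- colSums(sweep(sb, 2, g_new, "-")^2)
        d_new <- (b_pr + 0.5 * sse) / (nb / 2 + a_pr - 1)
        if (max(abs(g_new - g_star)) < 1e-10 && max(abs(d_new - d_star)) < 1e-10) {
          g_star <- g_new; d_star <- d_new
          break
        }
        g_star <- g_new; d_star <- d_new
      }
    } else if (is.finite(t2) && t2 > 1e-12) {
      # scale prior degenerate: shrink location only
      g_star <- (nb * t2 * g_hat + d_hat * g_bar) / (nb * t2 + d_hat)
    }
    out[ii, ] <- sweep(sweep(sb, 2, g_star, "-"), 2, sqrt(d_star), "/")
  }
  out <- sweep(sweep(out, 2, sqrt(var_pooled), "*"), 2, grand, "+")
  dimnames(out) <- dimnames(x)
  out
}

#' Harmonize a list of connectome matrices across batches
#'
#' Vectorizes each matrix's upper triangle into an edge-feature row,
#' harmonizes the stacked rows with [combat_harmonize()], and mirrors the
#' harmonized edges back into symmetric matrices with the original diagonal.
#'
#' @param matrices List of [connectome_matrix()]s of one kind and size.
#' @param batch Batch label per matrix.
#' @return List of symmetric matrices (plain), harmonized.
#' @export
harmonize_connectomes <- function(matrices, batch) {
  n <- nrow(matrices[[1]])
  stopifnot(all(vapply(matrices, nrow, integer(1)) == n))
  edges <- t(vapply(matrices, upper_tri_vec, numeric(n * (n - 1) / 2)))
  h <- combat_harmonize(edges, batch)
  lapply(seq_along(matrices), function(i) {
    vec_to_sym(h[i, ], n, diag_value = diag(unclass(matrices[[i]])))
  })
}
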