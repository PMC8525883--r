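# Training-set balancing and augmentation: Bayley-III scores are binned into
# five severity bins; synthetic subjects are convex combinations of a seed
# sample and its k nearest neighbours within the bin, applied to every
# modality and to the score with the same random simplex weights. Synthetic
# samples are for model training only, never validation or testing.

BIN_BREAKS <- c(40, 70, 80, 90, 100 + 1e-9, 160)
BIN_LABELS <- c("<70", "70-79", "80-89", "90-100", ">100")

#' Assign a Bayley-III score to its severity bin
#'
#' Five bins: `<70`, `70-79`, `80-89`, `90-100`, `>100`. Boundary
#' conventions make the five reported ranges a partition of `[40, 160]`:
#' `70-79` is `[70, 80)`, `90-100` is `[90, 100]` (inclusive at 100, following
#' the reported range), `>100` is `(100, 160]`.
#'
#' @param score Numeric score(s) in `[40, 160]`.
#' @return Integer bin id(s) in 1..5.
#' @export
assign_bin <- function(score) {
  if (any(!is.finite(score) | score < 40 | score > 160)) {
    stop("score(s) outside [40,160]: ",
         paste(utils::head(score[!is.finite(score) | score < 40 | score > 160], 5),
               collapse = ", "))
  }
  findInterval(score, BIN_BREAKS, rightmost.closed = TRUE)
}

#' Generate one synthetic subject as a convex combination of parents
#'
#' Weights beta over the seed sample and its k neighbours are drawn from the
#' flat Dirichlet (uniform over the simplex): all beta >= 0 and sum(beta) = 1.
#' Every modality tensor and the Bayley-III score receive the same
#' combination, so functional matrices stay symmetric with unit diagonal,
#' structural matrices stay in [0, 1], and the synthetic score lies between
#' the parents' extremes.
#'
#' @param x0 Seed [subject_record()], fully observed and scored.
#' @param neighbors List of neighbour records (possibly empty).
#' @param weights Optional explicit weight vector of length
#'   `1 + length(neighbors)` (checked to be a simplex point); drawn randomly
#'   when `NULL`.
#' @param id Identifier for the synthetic record.
#' @return A synthetic [subject_record()] with `synthetic = TRUE` and a
#'   `provenance` field holding parent ids and weights.
#' @export
synthesize <- function(x0, neighbors = list(), weights = NULL, id = NULL) {
  parents <- c(list(x0), neighbors)
  k1 <- length(parents)
  for (p in parents) {
    if (is.null(p$score)) stop("all parents must be scored")
  }
  if (is.null(weights)) {
    g <- stats::rexp(k1)
    weights <- g / sum(g)
  } else {
    stopifnot(length(weights) == k1)
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
      stop("weights must be non-negative and sum to 1")
    }
  }
  combine <- function(field) {
    vals <- lapply(parents, `[[`, field)
    if (any(vapply(vals, is.null, logical(1)))) {
      if (all(vapply(vals, is.null, logical(1)))) return(NULL)
      stop("parents disagree on presence of modality '", field, "'")
    }
    dims <- lapply(vals, function(v) if (is.matrix(v)) dim(v) else length(v))
    if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
      stop("dimension mismatch among parents for modality '", field, "'")
    }
    out <- vals[[1]] * weights[1]
    for (i in seq_len(k1 - 1L)) out <- out + vals[[i + 1L]] * weights[i + 1L]
    out
  }
  rec <- subject_record(
    subject_id = if (is.null(id)) paste0("syn_", x0$subject_id) else id,
    functional = combine("functional"), structural = combine("structural"),
    dwma = combine("dwma"), clinical = combine("clinical"),
    score = sum(vapply(parents, `[[`, numeric(1), "score") * weights),
    batch = x0$batch,
    dwma_length = if (!is.null(x0$dwma)) length(x0$dwma) else 11L,
    clinical_length = if (!is.null(x0$clinical)) length(x0$clinical) else 72L)
  rec$synthetic <- TRUE
  rec$provenance <- list(parents = vapply(parents, `[[`, character(1), "subject_id"),
                         weights = weights)
  # restore connectome classes (convexity preserves both invariant sets)
  if (!is.null(rec$functional)) {
    rec$functional <- connectome_matrix(rec$functional, "functional",
                                        expected_n = nrow(rec$functional))
  }
  if (!is.null(rec$structural)) {
    rec$structural <- connectome_matrix(rec$structural, "structural",
                                        expected_n = nrow(rec$structural))
  }
  rec
}

# z-score each column of each block and concatenate: the neighbour metric.
.flatten_for_distance <- function(records) {
  blocks <- list(
    functional = t(vapply(records, function(r) as.numeric(upper_tri_vec(r$functional)),
                          numeric(length(upper_tri_vec(records[[1]]$functional))))),
    structural = t(vapply(records, function(r) as.numeric(upper_tri_vec(r$structural)),
                          numeric(length(upper_tri_vec(records[[1]]$structural))))),
    dwma = t(vapply(records, function(r) as.numeric(r$dwma),
                    numeric(length(records[[1]]$dwma)))),
    clinical = t(vapply(records, function(r) as.numeric(r$clinical),
                        numeric(length(records[[1]]$clinical)))))
  do.call(cbind, lapply(blocks, function(b) {
    s <- apply(b, 2, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    sweep(sweep(b, 2, colMeans(b), "-"), 2, s, "/")
  }))
}

#' Balance score bins and expand the training set by synthesis
#'
#' Phase 1 equalizes the five bin counts by synthesizing into deficient bins:
#' a seed sample is drawn uniformly from the bin's original members and
#' combined with its k nearest original neighbours within the same bin
#' (Euclidean distance on the concatenated, block-z-scored flattened modality
#' vector). Phase 2 keeps synthesizing round-robin into the currently
#' smallest bins until the total reaches `multiplier` times the original
#' count. Originals are always retained; the output is shuffled.
#'
#' @param records List of fully observed, scored [subject_record()]s.
#' @param k Neighbour count (clamped to bin size - 1 with a warning).
#' @param multiplier Total-size multiplier (default 10).
#' @param seed RNG seed controlling weights, seeds and shuffling.
#' @return Shuffled list of records (originals + synthetic), attribute
#'   `n_synthetic`.
#' @export
balance_and_expand <- function(records, k = 5L, multiplier = 10L, seed = 1L) {
  stopifnot(length(records) >= 1, k >= 1, multiplier >= 1)
  scores <- vapply(records, function(r) {
    if (is.null(r$score)) stop("all training records must be scored") else r$score
  }, numeric(1))
  bins <- assign_bin(scores)
  present <- sort(unique(bins))
  missing_bins <- setdiff(1:5, present)
  if (length(missing_bins)) {
    stop("empty score bin(s): ", paste(BIN_LABELS[missing_bins], collapse = ", "))
  }
  feats <- .flatten_for_distance(records)
  by_bin <- split(seq_along(records), bins)
  n_orig <- length(records)
  target_total <- multiplier * n_orig
  with_seed(seed, {
    synth <- list()
    counts <- vapply(by_bin, length, integer(1))
    make_one <- function(bin_key) {
      members <- by_bin[[bin_key]]
      seed_idx <- members[sample.int(length(members), 1L)]
      kk <- min(k, length(members) - 1L)
      if (kk < k && length(members) - 1L < k) {
        # clamp silently after first warning per bin
        if (!isTRUE(attr(by_bin, paste0("warned_", bin_key)))) {
          warning("bin ", BIN_LABELS[as.integer(bin_key)], ": k clamped to ",
                  kk, " (bin size ", length(members), ")")
          attr(by_bin, paste0("warned_", bin_key)) <<- TRUE
        }
      }
      nbr <- integer(0)
      if (kk > 0) {
        others <- setdiff(members, seed_idx)
        d <- sqrt(colSums((t(feats[others, , drop = FALSE]) - feats[seed_idx, ])^2))
        nbr <- others[order(d)[seq_len(kk)]]
      }
      synthesize(records[[seed_idx]], records[nbr],
                 id = sprintf("syn_%05d", length(synth) + 1L))
    }
    # phase 1: equalize bins
    repeat {
      deficit <- max(counts) - counts
      if (all(deficit == 0)) break
      key <- names(counts)[which.max(deficit)]
      synth[[length(synth) + 1L]] <- make_one(key)
      counts[key] <- counts[key] + 1L
    }
    # phase 2: grow to target, keeping bins equal up to remainder
    while (n_orig + length(synth) < target_total) {
      key <- names(counts)[which.min(counts)]
      synth[[length(synth) + 1L]] <- make_one(key)
      counts[key] <- counts[key] + 1L
    }
    out <- c(records, synth)
    out <- out[sample.int(length(out))]
    attr(out, "n_synthetic") <- length(synth)
    out
  })
}
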