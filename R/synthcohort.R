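# Synthetic multimodal cohort generator with planted ground truth. A latent
# standard-normal risk variable z drives the Bayley-III score
# (score = 100 - g*z + noise, clipped to [40, 160]) and loads onto a chosen
# set of functional edges, structural edges, clinical features and the DWMA
# profile, so parameter-recovery and ordering claims can be tested without
# any real cohort. Functional matrices are built by correlating sampled
# time series from a z-dependent covariance, which guarantees genuine
# correlation matrices.

#' Design of a simulated multimodal cohort
#'
#' @param n_subjects Cohort size.
#' @param n_func_rois,n_struct_rois Parcellation sizes (223 and 90 at full
#'   scale; reduced sizes for desk-scale experiments).
#' @param t_points Time frames per subject for the functional channel.
#' @param n_clinical,n_dwma Tabular vector lengths (72 and 11 at full scale).
#' @param planted_func_edges data.frame `(i, j, effect)` — latent-risk
#'   loading on the correlation of edge (i, j), `i < j`.
#' @param planted_struct_edges data.frame `(i, j, effect)` — loading on FA
#'   edges.
#' @param informative_clinical data.frame `(index, effect)` — clinical
#'   features linearly loaded on z.
#' @param dwma_effect Relative increase of the normalized-DWMA profile per
#'   unit z (higher risk, more DWMA, lower score).
#' @param score_g Slope of the score on z (default 12).
#' @param score_sigma Score noise SD (default 10). With the defaults the
#'   high-risk (score <= 90) class is roughly a third of subjects.
#' @param batches Optional data.frame `(label, shift, scale)`: per-batch
#'   additive shift and multiplicative scale applied to edge features last
#'   (subjects are assigned round-robin). `NULL` for a single unbatched site.
#' @param modality_noise SD of per-modality latent distortion. With 0
#'   (default) every modality observes the same latent risk z (redundant
#'   signal); with tau > 0 modality m observes `z + d_m`,
#'   `d_m ~ N(0, tau^2)` drawn independently per subject and modality, so
#'   the modalities are complementary noisy views of z and combining them
#'   carries more information than any single one.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_subjects = 120L, n_func_rois = 223L,
                              n_struct_rois = 90L, t_points = 120L,
                              n_clinical = 72L, n_dwma = 11L,
                              planted_func_edges = NULL,
                              planted_struct_edges = NULL,
                              informative_clinical = NULL,
                              dwma_effect = 0, score_g = 12, score_sigma = 10,
                              batches = NULL, modality_noise = 0) {
  chk_edges <- function(e, n) {
    if (is.null(e)) return(invisible())
    stopifnot(all(e$i < e$j), all(e$i >= 1), all(e$j <= n))
  }
  chk_edges(planted_func_edges, n_func_rois)
  chk_edges(planted_struct_edges, n_struct_rois)
  if (!is.null(informative_clinical)) {
    stopifnot(all(informative_clinical$index >= 1),
              all(informative_clinical$index <= n_clinical))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_func_rois = as.integer(n_func_rois),
                 n_struct_rois = as.integer(n_struct_rois),
                 t_points = as.integer(t_points),
                 n_clinical = as.integer(n_clinical), n_dwma = as.integer(n_dwma),
                 planted_func_edges = planted_func_edges,
                 planted_struct_edges = planted_struct_edges,
                 informative_clinical = informative_clinical,
                 dwma_effect = dwma_effect, score_g = score_g,
                 score_sigma = score_sigma, batches = batches,
                 modality_noise = modality_noise),
            class = "simulation_design")
}

#' Reduced-size default design with planted multimodal signal
#'
#' The desk-scale study conditions used throughout the package's synthetic
#' experiments: 120 subjects, 32-ROI "functional" and 24-ROI "structural"
#' parcellations, five planted functional edges, four planted structural
#' edges, three informative clinical features, and a DWMA-score coupling.
#' Effects are complementary across modalities (each modality carries part
#' of the signal).
#' @param n_subjects Cohort size.
#' @return A [simulation_design()].
#' @export
reduced_design <- function(n_subjects = 120L) {
  simulation_design(
    n_subjects = n_subjects, n_func_rois = 32L, n_struct_rois = 24L,
    t_points = 120L, n_clinical = 72L, n_dwma = 11L,
    # planted edges are kept mutually separated by more than the Grad-CAM
    # point-spread width (about 5 matrix cells at the 14x14 last-conv
    # resolution), the design requirement for a well-posed recovery study
    planted_func_edges = data.frame(i = c(3L, 6L, 13L, 18L, 26L),
                                    j = c(10L, 22L, 29L, 24L, 31L),
                                    effect = 0.25),
    planted_struct_edges = data.frame(i = c(3L, 7L, 12L, 18L),
                                      j = c(15L, 21L, 22L, 23L),
                                      effect = 0.12),
    informative_clinical = data.frame(index = c(5L, 23L, 48L), effect = 1.0),
    dwma_effect = 0.35, score_g = 12, score_sigma = 10)
}

# deterministic base structures shared by all subjects of a design
.design_base <- function(design) {
  with_seed(derive_seed(90210, design$n_func_rois, design$n_struct_rois,
                        design$n_clinical), {
    nf <- design$n_func_rois
    # mild base functional covariance: low-rank community structure
    L <- matrix(stats::rnorm(nf * 3, sd = 0.4), nf, 3)
    sigma0 <- tcrossprod(L) + diag(nf)
    d <- 1 / sqrt(diag(sigma0))
    sigma0 <- sigma0 * tcrossprod(d)
    ns <- design$n_struct_rois
    base_fa <- matrix(0, ns, ns)
    ut <- which(upper.tri(base_fa))
    conn <- sample(ut, size = round(0.4 * length(ut)))
    base_fa[conn] <- stats::runif(length(conn), 0.15, 0.55)
    base_fa <- base_fa + t(base_fa)
    n_alpha <- design$n_dwma - 4L
    dwma_base <- 0.08 * exp(-2.5 * (seq_len(n_alpha) - 1) / max(1, n_alpha - 1))
    clin_type <- rep(c("continuous", "categorical"),
                     c(ceiling(design$n_clinical * 5 / 9),
                       design$n_clinical - ceiling(design$n_clinical * 5 / 9)))
    list(sigma0 = sigma0, base_fa = base_fa, dwma_base = dwma_base,
         clin_type = clin_type)
  })
}

.simulate_one <- function(design, base, z, id, batch_label = NULL) {
  # per-modality latent views: z_m = z + d_m when modality noise is enabled
  tau <- design$modality_noise %||% 0
  zm <- if (tau > 0) z + stats::rnorm(4, sd = tau) else rep(z, 4)
  names(zm) <- c("functional", "structural", "dwma", "clinical")
  nf <- design$n_func_rois
  sigma <- base$sigma0
  if (!is.null(design$planted_func_edges)) {
    e <- design$planted_func_edges
    tgt <- pmin(pmax(sigma[cbind(e$i, e$j)] + e$effect * zm[["functional"]], -0.95), 0.95)
    sigma[cbind(e$i, e$j)] <- tgt
    sigma[cbind(e$j, e$i)] <- tgt
    ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 1e-6) {
      # shrink toward the base covariance until feasible
      lam <- 1
      repeat {
        lam <- lam * 0.7
        s2 <- base$sigma0 + lam * (sigma - base$sigma0)
        if (min(eigen(s2, symmetric = TRUE, only.values = TRUE)$values) >= 1e-6) {
          sigma <- s2
          warning("planted functional effect shrunk to keep covariance PSD")
          break
        }
      }
    }
  }
  ts <- matrix(stats::rnorm(design$t_points * nf), design$t_points, nf) %*%
    chol(sigma)
  func <- functional_connectome(ts, expected_n = nf)

  ns <- design$n_struct_rois
  fa <- base$base_fa
  if (!is.null(design$planted_struct_edges)) {
    e <- design$planted_struct_edges
    # planted edges sit on a guaranteed mid-range base FA so the effect can
    # move them in both directions before clipping
    cur <- pmax(fa[cbind(e$i, e$j)], 0.35)
    fa[cbind(e$i, e$j)] <- cur + e$effect * zm[["structural"]]
    fa[cbind(e$j, e$i)] <- fa[cbind(e$i, e$j)]
  }
  noise <- matrix(0, ns, ns)
  noise[upper.tri(noise)] <- stats::rnorm(ns * (ns - 1) / 2,
                                          sd = design$struct_noise_sd %||% 0.03)
  fa <- fa + noise + t(noise)
  fa[fa != 0] <- pmin(pmax(fa[fa != 0], 0.01), 0.99)
  fa[fa < 0] <- 0
  diag(fa) <- 0
  struct <- connectome_matrix(fa, "structural", expected_n = ns)

  n_alpha <- design$n_dwma - 4L
  factor_sub <- pmax(0.1, 1 + design$dwma_effect * zm[["dwma"]] + stats::rnorm(1, sd = 0.1))
  ratios <- pmin(base$dwma_base * factor_sub, 1)
  wm <- 180000 * exp(stats::rnorm(1, sd = 0.08))
  gm <- 250000 * exp(stats::rnorm(1, sd = 0.08))
  csf <- 50000 * exp(stats::rnorm(1, sd = 0.12))
  dwma <- c(ratios, wm, gm, csf, wm + gm)
  names(dwma) <- c(sprintf("dwma_norm_%02d", seq_len(n_alpha)),
                   "wm_volume", "gm_volume", "csf_volume", "cerebral_volume")

  clin <- numeric(design$n_clinical)
  cont <- base$clin_type == "continuous"
  clin[cont] <- stats::rnorm(sum(cont))
  clin[!cont] <- stats::rbinom(sum(!cont), 1, 0.35)
  if (!is.null(design$informative_clinical)) {
    ic <- design$informative_clinical
    for (q in seq_len(nrow(ic))) {
      i <- ic$index[q]
      if (cont[i]) {
        clin[i] <- ic$effect[q] * zm[["clinical"]] + stats::rnorm(1, sd = 0.6)
      } else {
        clin[i] <- stats::rbinom(1, 1,
                                 stats::plogis(1.5 * ic$effect[q] * zm[["clinical"]] - 0.5))
      }
    }
  }
  names(clin) <- sprintf("clinical_%02d", seq_len(design$n_clinical))

  score <- min(max(100 - design$score_g * z +
                     stats::rnorm(1, sd = design$score_sigma), 40), 160)
  rec <- subject_record(id, functional = func, structural = struct,
                        dwma = dwma, clinical = clin, score = score,
                        batch = batch_label,
                        dwma_length = design$n_dwma,
                        clinical_length = design$n_clinical)
  if (!is.null(batch_label) && !is.null(design$batches)) {
    b <- design$batches[design$batches$label == batch_label, ]
    bump <- function(m, lo, hi) {
      v <- unclass(m)
      off <- upper.tri(v)
      v[off] <- pmin(pmax(v[off] * b$scale + b$shift, lo), hi)
      v[lower.tri(v)] <- t(v)[lower.tri(v)]
      v
    }
    # batch effects applied last; matrices may leave the exact correlation
    # manifold (that is precisely what harmonization later removes)
    fv <- bump(rec$functional, -1, 1); diag(fv) <- 1
    rec$functional <- structure(fv, kind = "functional",
                                class = class(rec$functional))
    sv <- bump(rec$structural, 0, 1); diag(sv) <- 0
    rec$structural <- structure(sv, kind = "structural",
                                class = class(rec$structural))
  }
  rec
}

#' Simulate a labeled multimodal cohort with known ground truth
#'
#' @param design A [simulation_design()].
#' @param seed RNG seed; the cohort is fully deterministic given
#'   design + seed.
#' @return List with `records` (list of [subject_record()]s) and `truth`
#'   (planted-signal registry: per-subject latent z, the planted edge and
#'   clinical-feature tables, and the score-model parameters).
#' @export
simulate_cohort <- function(design, seed = 1L) {
  base <- .design_base(design)
  batch_labels <- NULL
  if (!is.null(design$batches)) {
    batch_labels <- rep(design$batches$label, length.out = design$n_subjects)
  }
  with_seed(seed, {
    z <- stats::rnorm(design$n_subjects)
    records <- lapply(seq_len(design$n_subjects), function(s) {
      .simulate_one(design, base, z[s], sprintf("sub_%04d", s),
                    if (!is.null(batch_labels)) batch_labels[s] else NULL)
    })
    list(records = records,
         truth = list(z = z,
                      planted_func_edges = design$planted_func_edges,
                      planted_struct_edges = design$planted_struct_edges,
                      informative_clinical = design$informative_clinical,
                      dwma_effect = design$dwma_effect,
                      score_g = design$score_g,
                      score_sigma = design$score_sigma))
  })
}

#' Simulate an unlabeled cohort (pretraining stand-in)
#'
#' Same generative process as [simulate_cohort()] with the outcome scores
#' withheld, mirroring a large unannotated cohort used for unsupervised
#' pretraining.
#' @param design A [simulation_design()].
#' @param n Number of subjects (overrides the design's `n_subjects`).
#' @param seed RNG seed.
#' @return List of score-less [subject_record()]s.
#' @export
simulate_unlabeled <- function(design, n = design$n_subjects, seed = 2L) {
  design$n_subjects <- as.integer(n)
  cohort <- simulate_cohort(design, seed = seed)
  lapply(cohort$records, function(r) { r$score <- NULL; r })
}
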