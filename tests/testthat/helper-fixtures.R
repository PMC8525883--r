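# Shared fixtures, all generated in code.

# 3x3x3 toy T2 volume: cerebral intensities all 100 except two voxels at 200.
toy_dwma_volume <- function(bright_in_csf = FALSE) {
  intensity <- array(100, c(3, 3, 3))
  wm <- array(FALSE, c(3, 3, 3)); wm[1:2, , ] <- TRUE
  gm <- array(FALSE, c(3, 3, 3)); gm[3, , ] <- TRUE
  csf <- array(FALSE, c(3, 3, 3))
  if (bright_in_csf) {
    wm[1, 1, 1] <- wm[2, 1, 1] <- FALSE
    csf[1, 1, 1] <- csf[2, 1, 1] <- TRUE
  }
  intensity[1, 1, 1] <- 200
  intensity[2, 1, 1] <- 200
  list(intensity = intensity,
       seg = tissue_segmentation(wm, gm, csf, voxel_volume = 1))
}

# deterministic tiny cohort of fully observed scored records (reduced sizes)
tiny_cohort <- function(n = 12, seed = 7, n_func = 8L, n_struct = 6L,
                        n_dwma = 5L, n_clin = 6L, scores = NULL) {
  with_seed_local(seed, {
    lapply(seq_len(n), function(i) {
      ts <- matrix(rnorm(20 * n_func), 20, n_func)
      fc <- functional_connectome(ts, expected_n = n_func)
      s <- matrix(runif(n_struct^2, 0.1, 0.9), n_struct)
      s <- (s + t(s)) / 2; diag(s) <- 0
      sc <- connectome_matrix(s, "structural", expected_n = n_struct)
      subject_record(sprintf("t%03d", i), functional = fc, structural = sc,
                     dwma = sort(runif(n_dwma), decreasing = TRUE),
                     clinical = rnorm(n_clin),
                     score = if (is.null(scores)) runif(1, 55, 130) else scores[i],
                     dwma_length = n_dwma, clinical_length = n_clin)
    })
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# tiny extractor-free fusion model on explicit input dims (fast path used by
# gradient and training tests)
tiny_model <- function(channels = c("dwma", "clinical"), mode = "classify",
                       input_dims = list(dwma = 5L, clinical = 6L),
                       fc_widths = c(8L, 4L), dropout_rate = 0.2, seed = 1L) {
  fusion_model(channels, mode = mode, input_dims = input_dims,
               fc_widths = fc_widths, dropout_rate = dropout_rate,
               fusion_width = 4L, seed = seed)
}
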