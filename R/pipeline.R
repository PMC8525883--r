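# End-to-end pipeline wiring: simulate (or load) a cohort, train and
# evaluate a recipe under nested cross-validation, rank discriminative
# features, and write artifacts with a provenance record.

#' Run the full prediction pipeline on a simulated cohort
#'
#' Executes the stages in dependency order: cohort simulation, optional SSAE
#' pretraining on an unlabeled cohort, nested cross-validated evaluation of
#' the requested recipe, a final refit on the whole cohort, and gradient
#' interpretability (tabular ranking + Grad-CAM edge ranking). Every
#' artifact is stamped with the configuration hash and seed.
#'
#' @param cfg List with fields: `mode` (`"classify"`/`"regress"`), `design`
#'   (a [simulation_design()]; defaults to [reduced_design()]), `channels`,
#'   `repeats`, `folds`, `augment`, `pretrain_n` (0 to skip pretraining),
#'   `extractor_input_size`, `extractor_widths`, `train_cfg`.
#' @param seed Master seed.
#' @param out_dir Output directory (created); `NULL` to skip writing.
#' @return List with `report` (cv_report), `rankings`, `edges`, `provenance`.
#' @export
run_pipeline <- function(cfg = list(), seed = 1L, out_dir = NULL) {
  if (is.null(cfg$mode)) stop("config must declare mode ('classify' or 'regress')")
  design <- cfg$design %||% reduced_design()
  channels <- cfg$channels %||% CHANNEL_ORDER
  ext <- build_extractor(widths = cfg$extractor_widths %||% VGG_WIDTHS_REDUCED,
                         input_size = cfg$extractor_input_size %||% 64L,
                         seed = derive_seed(seed, 1))
  np_log("simulating cohort (n=%d, seed=%d)", design$n_subjects, seed)
  cohort <- simulate_cohort(design, seed = derive_seed(seed, 2))
  pretrained <- NULL
  pretrain_n <- cfg$pretrain_n %||% 0L
  if (pretrain_n > 0 && any(channels %in% c("functional", "structural"))) {
    np_log("pretraining connectome channels on %d unlabeled subjects", pretrain_n)
    unl <- simulate_unlabeled(design, n = pretrain_n, seed = derive_seed(seed, 3))
    probe <- fusion_model(channels, mode = cfg$mode, extractor = ext, seed = 1L,
                          dwma_dim = design$n_dwma, clinical_dim = design$n_clinical)
    Xu <- model_inputs(probe, unl)
    pretrained <- list()
    for (ch in intersect(channels, c("functional", "structural"))) {
      pretrained[[ch]] <- pretrain_ssae(Xu[[ch]],
                                        cfg = pretrain_config(seed = derive_seed(seed, 4)))
    }
  }
  recipe <- model_recipe(channels = channels, mode = cfg$mode, extractor = ext,
                         train_cfg = cfg$train_cfg %||% train_config(),
                         augment = cfg$augment, pretrained = pretrained)
  np_log("nested cross-validation (%d repeats x %d folds)",
         cfg$repeats %||% 2L, cfg$folds %||% 5L)
  report <- nested_cv(cohort$records, recipe, repeats = cfg$repeats %||% 2L,
                      folds = cfg$folds %||% 5L, seed = derive_seed(seed, 5))
  rankings <- NULL; edges <- NULL
  if (cfg$mode == "classify") {
    np_log("refitting on the full cohort for interpretability")
    fit <- .refit_full(cohort$records, recipe, seed = derive_seed(seed, 6))
    Xall <- fit$feats
    rankings <- list()
    for (ch in intersect(channels, c("dwma", "clinical"))) {
      rankings[[ch]] <- rank_tabular(fit$model, Xall, ch)
    }
    if ("functional" %in% channels) {
      fit$model$extractor <- ext
      maps <- lapply(cohort$records, function(r) gradcam(fit$model, r, "functional"))
      edges <- top_connections(maps, sprintf("ROI_%02d", seq_len(design$n_func_rois)),
                               top_n = 20L)
    }
  }
  prov <- list(seed = seed, mode = cfg$mode,
               channels = channels, n_subjects = design$n_subjects,
               config_hash = sprintf("%08x", sum(utf8ToInt(paste(
                 cfg$mode, paste(channels, collapse = ","),
                 design$n_subjects, sep = "|")) * 31L)),
               r_version = as.character(getRversion()),
               timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$per_fold, file.path(out_dir, "cv_per_fold.csv"),
                     row.names = FALSE)
    utils::write.csv(report$summary, file.path(out_dir, "cv_summary.csv"),
                     row.names = FALSE)
    if (!is.null(rankings)) {
      for (ch in names(rankings)) {
        utils::write.csv(rankings[[ch]],
                         file.path(out_dir, paste0("ranking_", ch, ".csv")),
                         row.names = FALSE)
      }
    }
    if (!is.null(edges)) {
      utils::write.csv(edges, file.path(out_dir, "top_edges.csv"), row.names = FALSE)
    }
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(report = report, rankings = rankings, edges = edges, provenance = prov)
}

# train one model on a train/validation split of the full cohort (used for
# the interpretability stage)
.refit_full <- function(records, recipe, seed = 1L, val_frac = 0.2) {
  scores <- vapply(records, `[[`, numeric(1), "score")
  cls <- as.character(risk_class(scores))
  probe <- fusion_model(recipe$channels, mode = recipe$mode,
                        extractor = recipe$extractor,
                        dwma_dim = length(records[[1]]$dwma),
                        clinical_dim = length(records[[1]]$clinical), seed = 1L)
  feats <- model_inputs(probe, records)
  n <- length(records)
  val <- with_seed(seed, sample.int(n, max(2L, round(val_frac * n))))
  tr <- setdiff(seq_len(n), val)
  model <- fusion_model(recipe$channels, mode = recipe$mode,
                        extractor = recipe$extractor,
                        input_dims = lapply(feats, ncol),
                        fc_widths = recipe$fc_widths, seed = seed)
  if (!is.null(recipe$pretrained)) {
    for (ch in names(recipe$pretrained)) {
      model <- transplant_encoder(model, ch, recipe$pretrained[[ch]])
    }
  }
  cfg <- recipe$train_cfg; cfg$seed <- seed
  y_tr <- if (recipe$mode == "classify") cls[tr] else scores[tr]
  y_val <- if (recipe$mode == "classify") cls[val] else scores[val]
  fit <- finetune(model, lapply(feats, function(m) m[tr, , drop = FALSE]), y_tr,
                  lapply(feats, function(m) m[val, , drop = FALSE]), y_val, cfg)
  list(model = fit$model, feats = feats, history = fit$history)
}
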