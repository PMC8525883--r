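# Model validation: nested cross-validation (per repeat, five stratified
# folds, each split 60% training / 20% validation / 20% testing), the metric
# suite (balanced accuracy, sensitivity, specificity, AUC; Pearson r, MAE,
# SD of absolute error), and the demographic / model-comparison statistics
# (two-sided Student's t-test, Pearson chi-squared).

#' Classification metric suite
#'
#' Sensitivity is the true-positive rate on the high-risk class, specificity
#' the true-negative rate on the low-risk class, balanced accuracy their
#' mean; rates are reported in percent. AUC uses the rank method with ties
#' averaged (equivalent to trapezoidal integration of the ROC curve).
#'
#' @param y_true Risk labels (`"high"`/`"low"` or a factor).
#' @param y_prob High-risk probabilities.
#' @param threshold Classification threshold on the high-risk probability.
#' @return List with `balanced_accuracy`, `sensitivity`, `specificity`
#'   (percent) and `auc` (`NA` with a warning when only one class is
#'   present).
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- as.character(y_true)
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% c("high", "low")))
  pred <- ifelse(y_prob >= threshold, "high", "low")
  tp <- sum(pred == "high" & y_true == "high")
  fn <- sum(pred == "low" & y_true == "high")
  tn <- sum(pred == "low" & y_true == "low")
  fp <- sum(pred == "high" & y_true == "low")
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  n_pos <- sum(y_true == "high"); n_neg <- sum(y_true == "low")
  if (n_pos == 0 || n_neg == 0) {
    warning("single-class truth: AUC undefined")
    auc <- NA_real_
  } else {
    r <- rank(y_prob)   # ties averaged
    auc <- (sum(r[y_true == "high"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  list(balanced_accuracy = mean(c(sens, spec)), sensitivity = sens,
       specificity = spec, auc = auc)
}

#' Regression metric suite
#'
#' @param y_true,y_pred Numeric vectors (at least 3 pairs).
#' @return List with Pearson `r` (`NA` with a warning for constant truth),
#'   `mae` (mean absolute error) and `sd_ae` (sample SD of the absolute
#'   errors).
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  ae <- abs(y_true - y_pred)
  if (stats::sd(y_true) == 0) {
    warning("constant truth: Pearson r undefined")
    r <- NA_real_
  } else if (stats::sd(y_pred) == 0) {
    r <- NA_real_
  } else {
    r <- stats::cor(y_true, y_pred)
  }
  list(r = r, mae = mean(ae), sd_ae = stats::sd(ae))
}

#' Stratified nested cross-validation split plan
#'
#' Per repeat, subjects are partitioned into `folds` stratified folds (by
#' risk class when scores are available). Fold f serves as the test set, the
#' next fold as validation, and the remaining folds as training — the
#' 60/20/20 split for five folds. Every subject is tested exactly once per
#' repeat.
#'
#' @param strata Factor/character used for stratification (e.g. risk class).
#' @param repeats,folds Plan dimensions.
#' @param seed Seed making fold assignment reproducible.
#' @return A `split_plan`: nested list `plan[[repeat]][[fold]]` with `train`,
#'   `validation`, `test` index vectors.
#' @export
split_plan <- function(strata, repeats = 50L, folds = 5L, seed = 1L) {
  n <- length(strata)
  strata <- as.factor(strata)
  if (any(table(strata) < folds)) {
    stop("stratification infeasible: every class needs >= ", folds, " subjects")
  }
  plan <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_id <- integer(n)
    with_seed(derive_seed(seed, r), {
      for (cl in levels(strata)) {
        idx <- sample(which(strata == cl))
        fold_id[idx] <- rep(seq_len(folds), length.out = length(idx))
      }
    })
    plan[[r]] <- lapply(seq_len(folds), function(f) {
      val_f <- f %% folds + 1L
      list(test = which(fold_id == f),
           validation = which(fold_id == val_f),
           train = which(!fold_id %in% c(f, val_f)))
    })
  }
  structure(list(plan = plan, repeats = repeats, folds = folds, seed = seed,
                 n = n), class = "split_plan")
}

#' Recipe describing one model variant for cross-validated evaluation
#'
#' @param channels Channels the model uses (the combined model uses all
#'   four; unimodal recipes use one).
#' @param mode `"classify"` or `"regress"`.
#' @param extractor Fixed extractor shared by the connectome channels.
#' @param fc_widths,fusion_width,dropout_rate Architecture settings.
#' @param train_cfg A [train_config()].
#' @param augment `NULL` to disable, or `list(k = 5, multiplier = 10)` to
#'   balance-and-expand each training fold (training only).
#' @param pretrained Optional named list of [pretrain_ssae()] results keyed
#'   by channel, transplanted before fine-tuning.
#' @param engine `"fusion"` (the network) or `"majority"` (a dummy baseline
#'   predicting the majority class probability, for harness checks).
#' @return A `model_recipe` list.
#' @export
model_recipe <- function(channels = CHANNEL_ORDER, mode = "classify",
                         extractor = NULL, fc_widths = c(64L, 16L),
                         fusion_width = 8L, dropout_rate = 0.2,
                         train_cfg = train_config(), augment = NULL,
                         pretrained = NULL, engine = c("fusion", "majority")) {
  structure(list(channels = channels, mode = mode, extractor = extractor,
                 fc_widths = fc_widths, fusion_width = fusion_width,
                 dropout_rate = dropout_rate, train_cfg = train_cfg,
                 augment = augment, pretrained = pretrained,
                 engine = match.arg(engine)),
            class = "model_recipe")
}

#' Nested cross-validated evaluation of a model recipe
#'
#' Per fold: the training portion is (optionally) balanced and expanded with
#' synthetic samples — synthesis is fit inside the training fold only, and
#' synthetic records never reach validation or test — pretrained encoders
#' are (optionally) transplanted, the model is fine-tuned with
#' validation-based selection, and the held-out test subjects are scored.
#' Metrics are aggregated as mean and SD over all fold-by-repeat
#' evaluations.
#'
#' @param records Labeled [subject_record()]s (real subjects).
#' @param recipe A [model_recipe()].
#' @param repeats,folds Cross-validation dimensions (5-fold, 50 repeats at
#'   full scale).
#' @param seed Master seed.
#' @param feature_cache Optional precomputed [model_inputs()]-style list for
#'   `records` (avoids recomputing extractor features across recipes).
#' @return A `cv_report`: `per_fold` data.frame, `summary` (mean, sd per
#'   metric), and the `split_plan` used.
#' @export
nested_cv <- function(records, recipe, repeats = 50L, folds = 5L, seed = 1L,
                      feature_cache = NULL) {
  scores <- vapply(records, function(r) {
    if (is.null(r$score)) stop("all records must be scored for evaluation")
    r$score
  }, numeric(1))
  if (any(vapply(records, function(r) isTRUE(r$synthetic), logical(1)))) {
    stop("synthetic records must not enter cross-validated evaluation")
  }
  cls <- risk_class(scores)
  plan <- split_plan(cls, repeats, folds, seed)
  feats <- feature_cache
  if (is.null(feats) && recipe$engine == "fusion") {
    probe <- fusion_model(recipe$channels, mode = recipe$mode,
                          extractor = recipe$extractor,
                          dwma_dim = length(records[[1]]$dwma),
                          clinical_dim = length(records[[1]]$clinical),
                          fc_widths = recipe$fc_widths, seed = 1L)
    feats <- model_inputs(probe, records)
  }
  per_fold <- list()
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      sp <- plan$plan[[r]][[f]]
      res <- .run_fold(records, feats, scores, cls, sp, recipe,
                       fold_seed = derive_seed(seed, r, f))
      per_fold[[length(per_fold) + 1L]] <-
        cbind(data.frame(repeat_id = r, fold = f), as.data.frame(res))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(colnames(per_fold), c("repeat_id", "fold"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_fold[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary, plan = plan,
                 recipe_channels = recipe$channels, mode = recipe$mode),
            class = "cv_report")
}

.run_fold <- function(records, feats, scores, cls, sp, recipe, fold_seed) {
  if (recipe$engine == "majority") {
    maj_p <- mean(cls[sp$train] == "high")
    if (recipe$mode == "classify") {
      return(classification_metrics(cls[sp$test], rep(maj_p, length(sp$test))))
    }
    return(regression_metrics(scores[sp$test],
                              rep(mean(scores[sp$train]), length(sp$test))))
  }
  sub <- function(idx) lapply(feats, function(m) m[idx, , drop = FALSE])
  X_tr <- sub(sp$train); y_tr_score <- scores[sp$train]
  if (!is.null(recipe$augment)) {
    aug <- balance_and_expand(records[sp$train],
                              k = recipe$augment$k %||% 5L,
                              multiplier = recipe$augment$multiplier %||% 10L,
                              seed = fold_seed)
    syn <- Filter(function(r) isTRUE(r$synthetic), aug)
    if (length(syn)) {
      probe <- list(channels = recipe$channels, extractor = recipe$extractor,
                    specs = lapply(stats::setNames(nm = recipe$channels), function(ch)
                      list(input_dim = ncol(feats[[ch]]))))
      X_syn <- model_inputs(structure(probe, class = "fusion_model"), syn)
      X_tr <- Map(rbind, X_tr, X_syn[recipe$channels])
      y_tr_score <- c(y_tr_score, vapply(syn, `[[`, numeric(1), "score"))
    }
  }
  model <- fusion_model(recipe$channels, mode = recipe$mode,
                        extractor = recipe$extractor,
                        input_dims = lapply(feats, ncol),
                        fc_widths = recipe$fc_widths,
                        fusion_width = recipe$fusion_width,
                        dropout_rate = recipe$dropout_rate, seed = fold_seed)
  if (!is.null(recipe$pretrained)) {
    for (ch in names(recipe$pretrained)) {
      model <- transplant_encoder(model, ch, recipe$pretrained[[ch]])
    }
  }
  cfg <- recipe$train_cfg
  cfg$seed <- fold_seed
  y_tr <- if (recipe$mode == "classify") as.character(risk_class(y_tr_score)) else y_tr_score
  y_val <- if (recipe$mode == "classify") as.character(cls[sp$validation]) else scores[sp$validation]
  fit <- finetune(model, X_tr, y_tr, sub(sp$validation), y_val, cfg)
  if (recipe$mode == "classify") {
    p <- predict_inputs(fit$model, sub(sp$test))[, "high"]
    classification_metrics(as.character(cls[sp$test]), p)
  } else {
    regression_metrics(scores[sp$test], predict_inputs(fit$model, sub(sp$test)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s | channels: %s | %d repeat(s) x %d fold(s)\n",
              x$mode, paste(x$recipe_channels, collapse = "+"),
              x$plan$repeats, x$plan$folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-sided Student's t-test between two metric distributions
#'
#' Classic two-sample t-test (equal variances), as used to compare
#' performance distributions of different feature sets. Significance
#' threshold 0.05 by convention.
#'
#' @param a,b Numeric vectors of per-run metric values (each of length >= 2).
#' @return List with `t`, `p`, `df`.
#' @export
compare_metric_distributions <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  res <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {
    # both sides constant: identical means -> no difference
    return(list(t = 0, p = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0,
                df = length(a) + length(b) - 2))
  }
  list(t = unname(res$statistic), p = res$p.value, df = unname(res$parameter))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction; p from the chi-squared distribution with one
#' degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return List with `statistic`, `p`, `df`.
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-squared test undefined: zero margin")
  }
  if (stats::chisq.test(table, correct = FALSE)$statistic == 0) {
    return(list(statistic = 0, p = 1, df = 1L))
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}
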