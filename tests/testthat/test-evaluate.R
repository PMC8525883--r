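test_that("classification metrics match hand-computed values", {
  perfect <- classification_metrics(c("high", "high", "low", "low"),
                                    c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$balanced_accuracy, 100)
  expect_equal(perfect$auc, 1)

  ties <- classification_metrics(c("high", "low", "high", "low"),
                                 rep(0.5, 4))
  expect_equal(ties$auc, 0.5)

  # exhaustive pair-counting oracle: 3 of 4 pairs correctly ordered
  m <- classification_metrics(c("high", "high", "low", "low"),
                              c(0.9, 0.4, 0.6, 0.1))
  expect_equal(m$auc, 0.75)
  expect_equal(m$sensitivity, 50)
  expect_equal(m$specificity, 50)
  expect_equal(m$balanced_accuracy, 50)

  expect_warning(s <- classification_metrics(rep("high", 3), c(0.9, 0.8, 0.7)),
                 "single-class")
  expect_true(is.na(s$auc))
})

test_that("rank AUC equals exhaustive pair counting and pROC on random inputs", {
  skip_if_not_installed("pROC")
  with_seed_local(81, {
    for (rep in 1:10) {
      n <- sample(6:30, 1)
      y <- sample(c("high", "low"), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c("high", "low")
      p <- round(runif(n), 2)  # rounding forces ties
      got <- classification_metrics(y, p)$auc
      pos <- p[y == "high"]; neg <- p[y == "low"]
      pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(got, mean(pairs), tolerance = 1e-12)
      ref <- suppressMessages(pROC::auc(pROC::roc(
        response = y, predictor = p, levels = c("low", "high"),
        direction = "<")))
      expect_equal(got, as.numeric(ref), tolerance = 1e-12)
    }
  })
})

test_that("regression metrics match closed forms", {
  y <- c(90, 100, 110, 95)
  id <- regression_metrics(y, y)
  expect_equal(id$r, 1); expect_equal(id$mae, 0); expect_equal(id$sd_ae, 0)

  centered <- y - mean(y)
  expect_equal(regression_metrics(centered, -centered)$r, -1)

  m <- regression_metrics(c(1, 2, 3, 4), c(3, 4, 5, 6))  # errors all 2
  expect_equal(m$mae, 2); expect_equal(m$sd_ae, 0)

  expect_warning(cc <- regression_metrics(rep(5, 4), c(1, 2, 3, 4)), "constant")
  expect_true(is.na(cc$r))
})

test_that("the split plan partitions every repeat and keeps folds disjoint", {
  strata <- rep(c("high", "low"), c(18, 32))
  plan <- split_plan(strata, repeats = 2, folds = 5, seed = 3)
  for (r in 1:2) {
    tested <- unlist(lapply(plan$plan[[r]], `[[`, "test"))
    expect_setequal(tested, 1:50)       # each subject tested exactly once
    expect_equal(length(tested), 50)
    for (f in 1:5) {
      sp <- plan$plan[[r]][[f]]
      expect_length(intersect(sp$test, sp$validation), 0)
      expect_length(intersect(sp$test, sp$train), 0)
      expect_length(intersect(sp$validation, sp$train), 0)
      expect_setequal(c(sp$test, sp$validation, sp$train), 1:50)
      # both classes in every test fold (stratification)
      expect_equal(sort(unique(strata[sp$test])), c("high", "low"))
    }
  }
  p2 <- split_plan(strata, repeats = 2, folds = 5, seed = 3)
  expect_identical(plan$plan, p2$plan)
  expect_error(split_plan(rep(c("high", "low"), c(3, 47)), folds = 5), "infeasible")
})

test_that("the majority-baseline recipe scores at chance on a balanced cohort", {
  scores <- rep(c(80, 100), 15)   # perfectly balanced classes
  recs <- tiny_cohort(30, seed = 82, scores = scores)
  rep_maj <- nested_cv(recs, model_recipe(engine = "majority"),
                       repeats = 2, folds = 5, seed = 4)
  expect_equal(nrow(rep_maj$per_fold), 10)
  expect_equal(mean(rep_maj$per_fold$balanced_accuracy), 50)
})

test_that("nested CV runs the fusion engine end to end and is reproducible", {
  recs <- tiny_cohort(30, seed = 83,
                      scores = rep(c(60, 75, 85, 95, 110), 6))
  recipe <- model_recipe(channels = c("dwma", "clinical"),
                         train_cfg = train_config(epochs = 4),
                         augment = list(k = 2, multiplier = 2))
  r1 <- suppressWarnings(nested_cv(recs, recipe, repeats = 1, folds = 5, seed = 6))
  expect_equal(nrow(r1$per_fold), 5)
  expect_true(all(r1$per_fold$balanced_accuracy >= 0 &
                    r1$per_fold$balanced_accuracy <= 100))
  expect_true(all(r1$per_fold$auc >= 0 & r1$per_fold$auc <= 1, na.rm = TRUE))
  r2 <- suppressWarnings(nested_cv(recs, recipe, repeats = 1, folds = 5, seed = 6))
  expect_identical(r1$per_fold, r2$per_fold)

  syn <- recs
  syn[[1]]$synthetic <- TRUE
  expect_error(nested_cv(syn, recipe, repeats = 1, folds = 5, seed = 6),
               "synthetic")
})

test_that("metric-distribution comparison is a two-sided Student's t-test", {
  expect_equal(compare_metric_distributions(c(1, 2, 3), c(1, 2, 3))$p, 1)
  shifted <- compare_metric_distributions(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 0.01)
  ab <- compare_metric_distributions(c(1, 5, 3), c(2, 2, 7))
  ba <- compare_metric_distributions(c(2, 2, 7), c(1, 5, 3))
  expect_equal(ab$p, ba$p)
  expect_equal(ab$t, -ba$t)
  # matches stats::t.test with equal variances
  ref <- t.test(c(1, 5, 3), c(2, 2, 7), var.equal = TRUE)
  expect_equal(ab$p, ref$p.value)
  both_const <- compare_metric_distributions(c(2, 2), c(2, 2))
  expect_equal(both_const$p, 1)
})

test_that("2x2 chi-squared uses no continuity correction", {
  hom <- chisq_2x2(matrix(10, 2, 2))
  expect_equal(hom$statistic, 0); expect_equal(hom$p, 1)
  tab <- matrix(c(27, 14, 20, 11), 2)
  got <- chisq_2x2(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$df, 1)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})
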