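make_features <- function(n, dims, seed, signal = TRUE) {
  # planted linear signal: class depends on a few coordinates of each block
  with_seed_local(seed, {
    z <- rnorm(n)
    X <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
    if (signal) {
      for (ch in names(X)) X[[ch]][, 1:2] <- X[[ch]][, 1:2] + 1.2 * z
    }
    score <- pmin(pmax(100 - 12 * z + rnorm(n, sd = 6), 40), 160)
    list(X = X, y = as.character(risk_class(score)), score = score, z = z)
  })
}

test_that("SSAE pretraining reduces reconstruction loss and yields 16-d encoders", {
  with_seed_local(61, H <- matrix(rnorm(200 * 40), 200, 40))
  pre <- pretrain_ssae(H, fc_widths = c(16L, 8L),
                       cfg = pretrain_config(epochs = 20, seed = 3))
  for (layer_losses in pre$history) {
    expect_lt(layer_losses[length(layer_losses)], layer_losses[1])
  }
  expect_equal(dim(pre$encoders[[1]]$W), c(40L, 16L))
  expect_equal(dim(pre$encoders[[2]]$W), c(16L, 8L))

  # default widths transplant into a connectome channel and give a 16-d code
  with_seed_local(62, H2 <- matrix(rnorm(80 * 30), 80, 30))
  pre2 <- pretrain_ssae(H2, cfg = pretrain_config(epochs = 5, seed = 4))
  m <- fusion_model("functional", input_dims = list(functional = 30L), seed = 1)
  m <- transplant_encoder(m, "functional", pre2)
  code <- neopredict:::forward_stack(m$stacks$functional,
                                     matrix(rnorm(30), 1, 30), FALSE)$out
  expect_length(code, 16)
})

test_that("an identity-capacity autoencoder drives reconstruction error to ~0", {
  # 1-d data away from the sigmoid's saturated range; two hidden units give
  # the encoder enough redundancy to escape a dead-ReLU initialization
  with_seed_local(63, x <- matrix(runif(120, 0.2, 0.8), 120, 1))
  cfg <- pretrain_config(learning_rate = 0.1, epochs = 50, sparsity_weight = 0,
                         seed = 1)
  fit <- with_seed_local(1, neopredict:::.train_sae(x, 2L, cfg, cfg$learning_rate))
  rec <- neopredict:::forward_stack(
    fit$dec, neopredict:::forward_stack(fit$enc, x, FALSE)$out, FALSE)$out
  expect_lt(mean((rec - x)^2), 1e-3)
})

test_that("learning-rate selection stays inside the documented candidate set", {
  with_seed_local(64, H <- matrix(rnorm(60 * 10), 60, 10))
  pre <- pretrain_ssae(H, fc_widths = c(6L),
                       cfg = pretrain_config(learning_rate = NULL, epochs = 10,
                                             seed = 6))
  expect_true(pre$selected_lr %in% c(0.001, 0.01, 0.1, 0.5))
})

test_that("fine-tuning optimizes the loss on separable data and stops early when flat", {
  d <- make_features(48, list(dwma = 5L, clinical = 6L), seed = 65)
  model <- tiny_model(dropout_rate = 0, seed = 2)
  tr <- 1:36; va <- 37:48
  fit <- finetune(model, lapply(d$X, function(m) m[tr, , drop = FALSE]), d$y[tr],
                  lapply(d$X, function(m) m[va, , drop = FALSE]), d$y[va],
                  train_config(learning_rate = 0.005, epochs = 12, seed = 3))
  expect_true(all(diff(fit$history$train_loss[1:5]) < 0))
  expect_lt(fit$history$train_loss[nrow(fit$history)], fit$history$train_loss[1])

  # when the validation loss changes by less than the tolerance for
  # `patience` consecutive epochs, training halts before the epoch budget
  fit0 <- finetune(model, lapply(d$X, function(m) m[tr, , drop = FALSE]), d$y[tr],
                   lapply(d$X, function(m) m[va, , drop = FALSE]), d$y[va],
                   train_config(learning_rate = 1e-5, epochs = 50,
                                early_stop_patience = 5, early_stop_tol = 1,
                                seed = 3))
  expect_lte(fit0$stopped_epoch, 6)
  expect_equal(nrow(fit0$history), fit0$stopped_epoch)

  expect_error(
    finetune(model, lapply(d$X, function(m) m[tr, , drop = FALSE]),
             rep("high", 36),
             lapply(d$X, function(m) m[va, , drop = FALSE]), d$y[va],
             train_config(epochs = 2)),
    "single-class")
  expect_error(
    finetune(model, d$X, d$y, lapply(d$X, function(m) m[0, , drop = FALSE]),
             character(0), train_config(epochs = 2)),
    "validation")
})

test_that("regression fine-tuning beats the constant-median baseline on planted signal", {
  d <- make_features(60, list(dwma = 5L, clinical = 6L), seed = 66)
  model <- tiny_model(mode = "regress", dropout_rate = 0, seed = 4)
  tr <- 1:45; va <- 46:60
  fit <- finetune(model, lapply(d$X, function(m) m[tr, , drop = FALSE]), d$score[tr],
                  lapply(d$X, function(m) m[va, , drop = FALSE]), d$score[va],
                  train_config(epochs = 40, seed = 5))
  pred <- predict_inputs(fit$model, lapply(d$X, function(m) m[va, , drop = FALSE]))
  baseline <- mean(abs(d$score[va] - median(d$score[tr])))
  expect_lt(mean(abs(d$score[va] - pred)), baseline)
})

test_that("fine-tuning is reproducible and leaves the extractor untouched", {
  d <- make_features(24, list(dwma = 5L, clinical = 6L), seed = 67)
  run <- function() {
    model <- tiny_model(seed = 9)
    finetune(model, lapply(d$X, function(m) m[1:16, , drop = FALSE]), d$y[1:16],
             lapply(d$X, function(m) m[17:24, , drop = FALSE]), d$y[17:24],
             train_config(epochs = 4, seed = 11))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(neopredict:::model_params(f1$model),
                   neopredict:::model_params(f2$model))

  ext <- build_extractor(VGG_WIDTHS_REDUCED, input_size = 32, seed = 5)
  recs <- tiny_cohort(10, seed = 68, n_dwma = 11, n_clin = 72,
                      scores = c(70, 95, 85, 100, 110, 60, 88, 92, 105, 80))
  m <- fusion_model(extractor = ext, seed = 2)
  X <- neopredict:::model_inputs(m, recs)
  y <- as.character(risk_class(vapply(recs, `[[`, numeric(1), "score")))
  fit <- finetune(m, lapply(X, function(z) z[1:8, , drop = FALSE]), y[1:8],
                  lapply(X, function(z) z[9:10, , drop = FALSE]), y[9:10],
                  train_config(epochs = 3, seed = 1))
  expect_identical(extractor_hash(fit$model$extractor), ext$hash)
})

test_that("architecture search enumerates the full depth-width grid and returns the best cell", {
  d <- make_features(24, list(dwma = 5L, clinical = 6L), seed = 69)
  cfg <- train_config(epochs = 3, seed = 1)
  # full grid: 4 depths x 4 shared widths = 16 candidates
  gs <- grid_search_architecture(d$X, d$y, depths = 1:4,
                                 widths = c(8L, 16L, 32L, 64L),
                                 n_rep = 1L, cfg = cfg, seed = 2)
  expect_equal(nrow(gs$results), 16L)
  expect_true(all(is.finite(gs$results$mean_val_loss)))

  # singleton grid returns that candidate
  gs1 <- grid_search_architecture(d$X, d$y, depths = 2, widths = 8L,
                                  n_rep = 1L, cfg = cfg, seed = 2)
  expect_equal(gs1$best_fc_widths, c(8L, 8L))

  gs2 <- grid_search_architecture(d$X, d$y, depths = 2, widths = c(8L, 16L),
                                  n_rep = 1L, cfg = cfg, seed = 2)
  gs3 <- grid_search_architecture(d$X, d$y, depths = 2, widths = c(8L, 16L),
                                  n_rep = 1L, cfg = cfg, seed = 2)
  expect_identical(gs2$results, gs3$results)
})

test_that("SSAE pretraining does not hurt fine-tuned validation loss (median over seeds)", {
  dims <- list(functional = 30L, clinical = 6L)
  diffs <- vapply(1:5, function(s) {
    d <- make_features(70, dims, seed = 600 + s)
    H <- d$X$functional
    pre <- pretrain_ssae(H, fc_widths = c(8L, 4L),
                         cfg = pretrain_config(epochs = 15, seed = s))
    build <- function() fusion_model(names(dims), input_dims = dims,
                                     fc_widths = c(8L, 4L), fusion_width = 4L,
                                     dropout_rate = 0, seed = s)
    tr <- 1:50; va <- 51:70
    cfg <- train_config(epochs = 10, seed = s)
    sub <- function(idx) lapply(d$X, function(m) m[idx, , drop = FALSE])
    f_pre <- finetune(transplant_encoder(build(), "functional", pre),
                      sub(tr), d$y[tr], sub(va), d$y[va], cfg)
    f_rnd <- finetune(build(), sub(tr), d$y[tr], sub(va), d$y[va], cfg)
    f_pre$best_val_loss - f_rnd$best_val_loss
  }, numeric(1))
  expect_lte(median(diffs), 0)
})
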