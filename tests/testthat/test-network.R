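test_that("convolution matches a brute-force oracle on a tiny input", {
  with_seed_local(51, {
    x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
    Wm <- matrix(rnorm(3 * 18), 3, 18)   # 3 filters, 3x3x2 each
    b <- rnorm(3)
  })
  out <- neopredict:::conv2d_relu(x, Wm, b, relu = FALSE)
  xp <- array(0, c(7, 7, 2)); xp[2:6, 2:6, ] <- x
  for (f in 1:3) for (i in 1:5) for (j in 1:5) {
    patch <- as.numeric(xp[i:(i + 2), j:(j + 2), ])  # ki, kj, c col-major
    expect_equal(out[i, j, f], sum(Wm[f, ] * patch) + b[f], tolerance = 1e-12)
  }
})

test_that("max pooling and unpooling route values and gradients to the argmax", {
  x <- array(0, c(4, 4, 1))
  x[, , 1] <- matrix(c(1, 5, 2, 0,
                       3, 4, 8, 7,
                       0, 1, 2, 3,
                       9, 6, 5, 4), 4, 4, byrow = TRUE)
  p <- neopredict:::maxpool2(x)
  expect_equal(p$out[, , 1], matrix(c(5, 8, 9, 5), 2, 2, byrow = TRUE))
  dy <- array(1:4, c(2, 2, 1))
  dx <- neopredict:::maxunpool2(dy, p$arg, dim(x))
  expect_equal(sum(dx), sum(1:4))
  expect_equal(dx[1, 2, 1], dy[1, 1, 1])  # gradient lands on the max location
  expect_equal(dx[4, 1, 1], dy[2, 1, 1])
})

test_that("bilinear resampling is the identity at matching size and exact on linear ramps", {
  with_seed_local(52, m <- matrix(rnorm(224 * 224), 224, 224))
  expect_equal(bilinear_resize(m, 224, 224), m)
  ramp <- outer(seq(0, 1, length.out = 16), rep(1, 16))
  up <- bilinear_resize(ramp, 32, 32)
  d <- diff(up[, 1])[3:29]                 # interior slope constant (edges clamp)
  expect_lt(max(abs(d - d[10])), 1e-9)
  expect_gte(min(up), min(ramp)); expect_lte(max(up), max(ramp))
})

test_that("prepare_input maps ranges, resamples and standardizes deterministically", {
  z <- connectome_matrix(matrix(0, 8, 8), "structural", expected_n = 8)
  t_z <- prepare_input(z, size = 16)
  expect_equal(dim(t_z), c(16L, 16L, 3L))
  expect_true(all(t_z == (0 - 0.5) / 0.25))      # constant input stays constant
  expect_equal(t_z[, , 1], t_z[, , 3])

  id <- connectome_matrix(diag(8), "functional", expected_n = 8)
  t_id <- prepare_input(id, size = 8)            # same-size resample: identity
  expect_equal(t_id[, , 1], ((diag(8) + 1) / 2 - 0.5) / 0.25)

  expect_identical(prepare_input(id, 16), prepare_input(id, 16))
  bad <- id; bad[1, 2] <- NA
  expect_error(prepare_input(bad, 16), "non-finite")
})

test_that("the extractor mirrors the reference conv-pool architecture", {
  ext <- build_extractor(VGG_WIDTHS_FULL, input_size = 224, seed = 3)
  sh <- extractor_shape(ext)
  expect_equal(sh$n_conv, 16L)
  expect_equal(sh$n_pool, 5L)
  # 224 halved five times is 7; 512 maps of 7x7 flatten to 25088
  expect_equal(sh$out_size, 7L)
  expect_equal(sh$flat_length, 25088)
  expect_equal(vapply(ext$layers, function(l) nrow(l$W), numeric(1)),
               VGG_WIDTHS_FULL)

  # seeded construction is bit-reproducible
  ext2 <- build_extractor(VGG_WIDTHS_FULL, input_size = 224, seed = 3)
  expect_identical(ext$layers, ext2$layers)
  expect_identical(ext$hash, ext2$hash)
})

test_that("channel embeddings and the fusion head have the documented widths", {
  ext <- build_extractor(VGG_WIDTHS_REDUCED, input_size = 32, seed = 5)
  m <- fusion_model(extractor = ext, seed = 8)
  r <- tiny_cohort(1, seed = 53, n_func = 8, n_struct = 6,
                   n_dwma = 11, n_clin = 72)[[1]]
  # reduced cohort matrices still feed the full-size pipeline after resampling
  emb <- encode_channel(m, "functional", r)
  expect_length(emb, 16)
  expect_length(encode_channel(m, "clinical", r), 16)
  # evaluation mode is deterministic
  expect_identical(emb, encode_channel(m, "functional", r))
  expect_equal(m$fusion_in, 64L)
  expect_equal(dim(m$fusion_stack[[1]]$W), c(64L, 8L))
  expect_equal(dim(m$head[[1]]$W), c(8L, 2L))

  p <- predict_record(m, r)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  r2 <- r; r2$structural <- NULL
  expect_error(predict_record(m, r2), "structural")

  reg <- fusion_model(extractor = ext, mode = "regress", seed = 8)
  expect_true(is.finite(predict_record(reg, r)))
  expect_equal(dim(reg$head[[1]]$W), c(8L, 1L))
})

test_that("trainable parameter count is independent of the extractor weight source", {
  ext_a <- build_extractor(VGG_WIDTHS_REDUCED, input_size = 32, seed = 5)
  w <- lapply(ext_a$layers, function(l) list(W = l$W * 0 + 0.01, b = l$b))
  ext_b <- build_extractor(VGG_WIDTHS_REDUCED, input_size = 32,
                           weight_source = "pretrained", weights = w)
  count <- function(model) {
    sum(vapply(rapply(neopredict:::model_params(model), length, how = "unlist"),
               as.numeric, numeric(1)))
  }
  m_a <- fusion_model(extractor = ext_a, seed = 1)
  m_b <- fusion_model(extractor = ext_b, seed = 1)
  expect_equal(count(m_a), count(m_b))
})

test_that("fully connected stacks backpropagate exact gradients", {
  # central-difference check through dense + BN (eval mode) + ReLU
  with_seed_local(54, {
    model <- tiny_model(fc_widths = c(6L, 3L), dropout_rate = 0)
    X <- list(dwma = matrix(rnorm(3 * 5), 3, 5),
              clinical = matrix(rnorm(3 * 6), 3, 6))
  })
  fwd <- neopredict:::model_forward(model, X, training = FALSE)
  d_logits <- matrix(0, 3, 2); d_logits[, 1] <- 1
  bwd <- neopredict:::model_backward(model, fwd$caches, d_logits)
  s_of <- function(Xp) {
    sum(neopredict:::model_forward(model, Xp, training = FALSE)$logits[, 1])
  }
  h <- 1e-5
  for (probe in list(c("dwma", 1, 2), c("clinical", 2, 4), c("dwma", 3, 5))) {
    ch <- probe[1]; i <- as.integer(probe[2]); j <- as.integer(probe[3])
    Xp <- X; Xm <- X
    Xp[[ch]][i, j] <- Xp[[ch]][i, j] + h
    Xm[[ch]][i, j] <- Xm[[ch]][i, j] - h
    num <- (s_of(Xp) - s_of(Xm)) / (2 * h)
    expect_equal(bwd$dX[[ch]][i, j], num, tolerance = 1e-4)
  }
})
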