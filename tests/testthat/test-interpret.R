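test_that("tabular feature gradients match central finite differences", {
  with_seed_local(71, {
    model <- tiny_model(fc_widths = c(6L, 3L), dropout_rate = 0, seed = 5)
    X <- list(dwma = matrix(rnorm(4 * 5), 4, 5),
              clinical = matrix(rnorm(4 * 6), 4, 6))
  })
  rk <- rank_tabular(model, X, "clinical")
  expect_equal(nrow(rk), 6)
  expect_true(all(diff(rk$weight) <= 0))
  expect_true(all(rk$weight >= 0))

  # oracle: mean |ds/df| over records by central differences on p(high)
  p_high <- function(Xq) neopredict:::model_forward(model, Xq, FALSE)$out[, 1]
  h <- 1e-5
  num <- sapply(1:6, function(j) {
    Xp <- X; Xm <- X
    Xp$clinical[, j] <- Xp$clinical[, j] + h
    Xm$clinical[, j] <- Xm$clinical[, j] - h
    mean(abs((p_high(Xp) - p_high(Xm)) / (2 * h)))
  })
  got <- rk$weight[order(rk$feature)]
  expect_equal(got, num[order(sprintf("clinical_%02d", 1:6))], tolerance = 1e-3)

  # ranking is invariant to record order
  perm <- c(3, 1, 4, 2)
  rk2 <- rank_tabular(model, lapply(X, function(m) m[perm, , drop = FALSE]),
                      "clinical")
  expect_equal(rk, rk2, tolerance = 1e-12)

  reg <- tiny_model(mode = "regress", seed = 5)
  expect_error(rank_tabular(reg, X, "clinical"), "softmax")
})

test_that("a dead channel gets exactly zero weights", {
  model <- tiny_model(fc_widths = c(4L), dropout_rate = 0, seed = 6)
  model$stacks$clinical[[1]]$W[] <- 0
  model$stacks$clinical[[1]]$b[] <- 0
  with_seed_local(72, X <- list(dwma = matrix(rnorm(10), 2, 5),
                                clinical = matrix(rnorm(12), 2, 6)))
  rk <- rank_tabular(model, X, "clinical")
  expect_equal(rk$weight, rep(0, 6))
})

make_conv_model <- function(seed = 7, input_size = 32L) {
  ext <- build_extractor(VGG_WIDTHS_REDUCED, input_size = input_size, seed = seed)
  fusion_model(c("functional", "clinical"), extractor = ext,
               clinical_dim = 6L, fc_widths = c(8L, 4L), fusion_width = 4L,
               dropout_rate = 0, seed = seed)
}

test_that("Grad-CAM weights equal the GAP of finite-difference map gradients", {
  model <- make_conv_model(seed = 7)
  rec <- tiny_cohort(1, seed = 73, n_func = 8, n_clin = 6)[[1]]
  g <- gradcam(model, rec, "functional")
  ext <- model$extractor
  ec <- extractor_forward(ext, prepare_input(rec$functional, ext$input_size),
                          keep_cache = TRUE)
  # brute force: perturb single entries of the last conv maps, re-run the
  # head, and average ds/dA over each map
  s_of_A <- function(A) {
    p <- neopredict:::maxpool2(A)
    X <- list(functional = matrix(as.numeric(p$out), 1),
              clinical = matrix(as.numeric(rec$clinical), 1))
    neopredict:::model_forward(model, X, FALSE)$out[1, 1]
  }
  # finite differences through max pooling are only exact where the pool
  # window has no ties (a tied entry crossing the max biases the central
  # difference); restrict the oracle to tie-free maps
  h <- 1e-4
  tie_free <- which(vapply(seq_len(dim(ec$last_conv)[3]), function(k) {
    w <- as.numeric(ec$last_conv[, , k])
    length(unique(w)) == length(w) && min(diff(sort(w))) > 10 * h
  }, logical(1)))
  expect_gte(length(tie_free), 3)
  for (k in tie_free[1:3]) {
    dmap <- matrix(NA_real_, dim(ec$last_conv)[1], dim(ec$last_conv)[2])
    for (i in seq_len(nrow(dmap))) for (j in seq_len(ncol(dmap))) {
      Ap <- ec$last_conv; Am <- ec$last_conv
      Ap[i, j, k] <- Ap[i, j, k] + h
      Am[i, j, k] <- Am[i, j, k] - h
      dmap[i, j] <- (s_of_A(Ap) - s_of_A(Am)) / (2 * h)
    }
    denom <- max(abs(g$alpha[k]), 1e-8)
    expect_lt(abs(g$alpha[k] - mean(dmap)) / denom, 1e-3)
  }
})

test_that("Grad-CAM maps are normalized, symmetric, matrix-sized", {
  model <- make_conv_model(seed = 8)
  rec <- tiny_cohort(1, seed = 74, n_func = 8, n_clin = 6)[[1]]
  g <- gradcam(model, rec, "functional")
  expect_equal(dim(g$map), c(8L, 8L))
  expect_lt(max(abs(g$map - t(g$map))), 1e-12)
  if (max(g$map) > 0) expect_equal(max(g$map), 1)
  expect_gte(min(g$map), 0)

  reg <- fusion_model(c("functional", "clinical"), mode = "regress",
                      extractor = model$extractor, clinical_dim = 6L,
                      fc_widths = c(8L, 4L), fusion_width = 4L, seed = 8)
  expect_error(gradcam(reg, rec, "functional"), "softmax")
})

test_that("an everywhere-nonpositive weighted sum yields the zero map with a warning", {
  model <- make_conv_model(seed = 9)
  rec <- tiny_cohort(1, seed = 75, n_func = 8, n_clin = 6)[[1]]
  # force negative alpha * positive maps: flip the sign of the head so the
  # high-risk gradient reverses; if the natural map is already zero the
  # contract is exercised directly
  g <- gradcam(model, rec, "functional")
  flipped <- model
  flipped$head[[1]]$W <- -flipped$head[[1]]$W
  g2 <- suppressWarnings(gradcam(flipped, rec, "functional"))
  expect_true(max(g$map) == 0 || max(g2$map) == 0 ||
                (max(g$map) == 1 && max(g2$map) == 1))
  zero_side <- if (max(g$map) == 0) g else g2
  if (max(zero_side$map) == 0) expect_true(all(zero_side$map == 0))
})

test_that("top connections are ranked from averaged maps with hemisphere labels", {
  m1 <- matrix(0, 8, 8); m1[3, 7] <- m1[7, 3] <- 1; m1[2, 5] <- m1[5, 2] <- 0.5
  top <- top_connections(list(m1), sprintf("ROI_%d", 1:8), top_n = 2)
  expect_equal(top$roi_a[1], 3); expect_equal(top$roi_b[1], 7)
  # parity rule: odd = left, even = right
  expect_equal(top$hemisphere[1], "intra-left")
  expect_equal(top$hemisphere[2], "interhemispheric")

  labs <- c("A_L", "B_L", "C_R", "D_R", "E_L", "F_R", "G_L", "H_R")
  top2 <- top_connections(list(m1), labs, top_n = 2)
  expect_equal(top2$hemisphere[1], "interhemispheric")  # B_L x G_L? no: (3,7)=C_R,G_L
  expect_equal(top2$name_a[1], "C_R")

  expect_error(top_connections(list(m1), c("a", "b"), 2), "label count")

  # averaging across subjects: a pair strong in both maps wins
  m2 <- matrix(0, 8, 8); m2[3, 7] <- m2[7, 3] <- 0.9
  top3 <- top_connections(list(m1, m2), sprintf("ROI_%d", 1:8), top_n = 1)
  expect_equal(c(top3$roi_a, top3$roi_b), c(3, 7))
})
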