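test_that("simulation is fully deterministic under a fixed seed", {
  d <- reduced_design(8)
  c1 <- suppressWarnings(simulate_cohort(d, seed = 5))
  c2 <- suppressWarnings(simulate_cohort(d, seed = 5))
  expect_identical(c1$truth$z, c2$truth$z)
  expect_identical(lapply(c1$records, `[[`, "score"),
                   lapply(c2$records, `[[`, "score"))
  expect_identical(unclass(c1$records[[3]]$functional),
                   unclass(c2$records[[3]]$functional))
  c3 <- suppressWarnings(simulate_cohort(d, seed = 6))
  expect_false(identical(c1$truth$z, c3$truth$z))
})

test_that("generated records satisfy every modality invariant", {
  d <- reduced_design(15)
  co <- suppressWarnings(simulate_cohort(d, seed = 7))
  for (r in co$records) {
    f <- unclass(r$functional)
    expect_equal(diag(f), rep(1, d$n_func_rois))
    expect_lt(max(abs(f - t(f))), 1e-9)
    ev <- min(eigen(f, symmetric = TRUE, only.values = TRUE)$values)
    expect_gt(ev, -1e-8)
    s <- unclass(r$structural)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(diag(s), rep(0, d$n_struct_rois))
    expect_true(all(diff(r$dwma[1:7]) <= 1e-12))   # profile non-increasing
    expect_length(r$clinical, 72)
    expect_gte(r$score, 40); expect_lte(r$score, 160)
  }
})

test_that("a null design produces no edge-outcome association", {
  d <- simulation_design(n_subjects = 200, n_func_rois = 12, n_struct_rois = 8,
                         t_points = 100)
  co <- simulate_cohort(d, seed = 9)
  cls <- as.numeric(risk_class(vapply(co$records, `[[`, numeric(1), "score")) == "high")
  ut <- which(upper.tri(matrix(0, 12, 12)), arr.ind = TRUE)
  rs <- apply(ut, 1, function(p) {
    edge <- vapply(co$records, function(r) r$functional[p[1], p[2]], numeric(1))
    abs(cor(edge, cls))
  })
  # null association: every edge stays inside the n = 200 sampling band and
  # the cohort-average |r| sits at the chance level
  expect_lt(max(rs), 4 / sqrt(200))
  expect_lt(mean(rs), 0.08)
})

test_that("a strongly planted functional edge dominates the group difference", {
  d <- simulation_design(n_subjects = 200, n_func_rois = 12, n_struct_rois = 8,
                         t_points = 100,
                         planted_func_edges = data.frame(i = 3, j = 9,
                                                         effect = 0.3))
  co <- suppressWarnings(simulate_cohort(d, seed = 10))
  z <- co$truth$z
  tstat <- function(i, j) {
    edge <- vapply(co$records, function(r) r$functional[i, j], numeric(1))
    grp <- z > 0
    unname(abs(t.test(edge[grp], edge[!grp])$statistic))
  }
  planted <- tstat(3, 9)
  ut <- which(upper.tri(matrix(0, 12, 12)), arr.ind = TRUE)
  others <- ut[!(ut[, 1] == 3 & ut[, 2] == 9), , drop = FALSE]
  other_t <- apply(others, 1, function(p) tstat(p[1], p[2]))
  expect_gt(planted, max(other_t))
})

test_that("unlabeled simulation matches the labeled generator", {
  d <- reduced_design(20)
  unl <- suppressWarnings(simulate_unlabeled(d, n = 25, seed = 11))
  expect_length(unl, 25)
  expect_true(all(vapply(unl, function(r) is.null(r$score), logical(1))))
  u2 <- suppressWarnings(simulate_unlabeled(d, n = 25, seed = 11))
  expect_identical(lapply(unl, `[[`, "functional"),
                   lapply(u2, `[[`, "functional"))

  # same generative process: cohort-mean edge strength agrees within 2 SE
  d2 <- simulation_design(n_subjects = 200, n_func_rois = 10, n_struct_rois = 6,
                          t_points = 80)
  lab <- simulate_cohort(d2, seed = 12)$records
  un <- simulate_unlabeled(d2, n = 200, seed = 13)
  edge_means <- function(recs) {
    vapply(recs, function(r) mean(neopredict:::upper_tri_vec(unclass(r$functional))), numeric(1))
  }
  a <- edge_means(lab); b <- edge_means(un)
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 2 * se + 1e-8)
})

test_that("batch effects shift edges and ComBat pulls the batches back together", {
  d <- simulation_design(n_subjects = 60, n_func_rois = 10, n_struct_rois = 6,
                         t_points = 80,
                         batches = data.frame(label = c("siteA", "siteB"),
                                              shift = c(0, 0.15),
                                              scale = c(1, 1)))
  co <- simulate_cohort(d, seed = 14)
  batch <- vapply(co$records, `[[`, character(1), "batch")
  edges <- t(vapply(co$records,
                    function(r) neopredict:::upper_tri_vec(unclass(r$functional)),
                    numeric(45)))
  raw_gap <- mean(colMeans(edges[batch == "siteB", ]) -
                    colMeans(edges[batch == "siteA", ]))
  expect_gt(raw_gap, 0.05)
  h <- combat_harmonize(edges, batch)
  post_gap <- mean(abs(colMeans(h[batch == "siteB", ]) -
                         colMeans(h[batch == "siteA", ])))
  expect_lt(post_gap, 0.02)
})

test_that("upper-tri vectorization helpers invert each other", {
  with_seed_local(92, v <- runif(15))
  m <- neopredict:::vec_to_sym(v, 6, diag_value = 1)
  expect_equal(neopredict:::upper_tri_vec(m), v)
  expect_equal(diag(m), rep(1, 6))
  expect_equal(m, t(m))
})
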