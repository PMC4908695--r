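test_that("PCA recovers hand-computable structure and variance partitions", {
  # identical rows: no variance at all
  flat <- run_pca(matrix(1, 5, 4), n_axes = 2)
  expect_equal(flat$axis_variance_fraction, c(0, 0))
  expect_equal(max(abs(flat$scores)), 0)

  # 2x2 toy [[0,2],[2,0]]: PC1 carries 100% of the variance
  toy <- suppressWarnings(run_pca(matrix(c(0, 2, 2, 0), 2, 2), n_axes = 1))
  expect_equal(toy$axis_variance_fraction, 1)
  expect_equal(sort(abs(toy$scores[, 1])), c(sqrt(2), sqrt(2)))

  # variance fractions over a leading subset never exceed 1
  set.seed(3)
  x <- matrix(rnorm(30 * 8), 30, 8)
  p <- run_pca(x, n_axes = 5)
  expect_true(all(diff(p$axis_variance_fraction) <= 1e-12))
  expect_lte(sum(p$axis_variance_fraction), 1 + 1e-12)

  # all axes retained reproduce pairwise Euclidean distances (Eckart-Young)
  pfull <- run_pca(x, n_axes = 8)
  expect_equal(
    as.matrix(dist(pfull$scores)),
    as.matrix(dist(scale(x, scale = FALSE))),
    tolerance = 1e-8, ignore_attr = TRUE
  )
})

test_that("Procrustes correlation is exact under similarity transforms and symmetric", {
  set.seed(10)
  x <- matrix(rnorm(40), 20, 2)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  y <- 3.2 * x %*% rot + matrix(c(5, -2), 20, 2, byrow = TRUE)
  expect_equal(procrustes_correlation(x, y), 1, tolerance = 1e-12)
  # symmetry
  a <- matrix(rnorm(60), 30, 2)
  b <- matrix(rnorm(60), 30, 2)
  expect_equal(procrustes_correlation(a, b), procrustes_correlation(b, a),
    tolerance = 1e-12
  )
  expect_error(procrustes_correlation(matrix(1, 10, 2), a), "zero variance")
})

test_that("Procrustes correlation matches the vegan protest statistic", {
  skip_if_not_installed("vegan")
  set.seed(21)
  x <- matrix(rnorm(60), 30, 2)
  y <- x + matrix(rnorm(60, sd = 0.6), 30, 2)
  ours <- procrustes_correlation(x, y)
  ref <- sqrt(1 - vegan::procrustes(x, y, symmetric = TRUE)$ss)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("Procrustes permutation test behaves at both extremes", {
  set.seed(2)
  x <- matrix(rnorm(60), 30, 2)
  res <- procrustes_permutation_test(x, x + rnorm(60, sd = 0.01),
    n_perm = 999, seed = 5
  )
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$observed, 0.99)
  null_res <- procrustes_permutation_test(
    matrix(rnorm(60), 30, 2), matrix(rnorm(60), 30, 2),
    n_perm = 199, seed = 6
  )
  expect_gt(null_res$p_value, 0.001)
  expect_lte(null_res$p_value, 1)
})

test_that("pair-sharing test flags tight clusters and rejects degenerate groupings", {
  scores <- two_blob_scores(15, sep = 30, seed = 4)
  groups <- rep(c("a", "b"), each = 15)
  res <- pair_sharing_distance_test(scores, groups, n_perm = 1000, seed = 1)
  expect_equal(res$p_value, 1 / 1001)
  expect_equal(res$tail, "lower")
  # shuffled labels destroy the signal
  set.seed(8)
  res2 <- pair_sharing_distance_test(scores, sample(groups), n_perm = 500, seed = 2)
  expect_gt(res2$p_value, 0.01)
  expect_error(
    pair_sharing_distance_test(scores, seq_len(30), n_perm = 10, seed = 1),
    "shares a group"
  )
  expect_error(
    pair_sharing_distance_test(scores, rep("a", 30), n_perm = 10, seed = 1),
    "degenerate"
  )
})

test_that("PERMANOVA matches the literal distance-matrix partition and vegan", {
  set.seed(12)
  scores <- matrix(rnorm(80), 40, 2)
  groups <- rep(letters[1:4], each = 10)
  ours <- permanova(scores, groups, n_perm = 99, seed = 3)
  oracle <- bf_permanova_dist(scores, groups)
  expect_equal(ours$R2, oracle$R2, tolerance = 1e-10)
  expect_equal(ours$pseudo_F, oracle$F, tolerance = 1e-10)
  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(dist(scores) ~ g, data = data.frame(g = groups),
    permutations = 49
  )
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA separates perfect clusters and handles unbalanced groups", {
  scores <- two_blob_scores(12, sep = 50, seed = 9)
  groups <- rep(c("x", "y"), each = 12)
  res <- permanova(scores, groups, n_perm = 999, seed = 7)
  expect_gt(res$R2, 0.97)
  expect_equal(res$test$p_value, 1 / 1000)
  # unbalanced grouping still matches the brute-force partition
  ub <- c(rep("x", 5), rep("y", 19))
  res_ub <- permanova(scores, ub, n_perm = 49, seed = 1)
  expect_equal(res_ub$R2, bf_permanova_dist(scores, ub)$R2, tolerance = 1e-10)
  expect_error(permanova(scores, rep("x", 24), n_perm = 9), "two groups")
})

test_that("RDA recognizes pure-signal and pure-noise predictor relationships", {
  set.seed(30)
  n <- 25
  pred <- cbind(runif(n), runif(n))
  # response exactly linear in predictors -> constrained axes capture all variance
  y_lin <- pred %*% matrix(rnorm(2 * 6), 2, 6)
  fit <- rda_fit(y_lin, pred)
  expect_equal(attr(fit, "constrained_fraction"), 1, tolerance = 1e-10)
  # response orthogonal to predictors -> essentially nothing constrained
  y_noise <- matrix(rnorm(n * 6), n, 6)
  y_orth <- qr.resid(qr(cbind(1, pred)), y_noise)
  fit0 <- rda_fit(y_orth, pred)
  expect_lt(attr(fit0, "constrained_fraction"), 1e-10)
  # constrained variance never exceeds the unconstrained PCA variance
  y <- matrix(rnorm(n * 10), n, 10)
  rda_frac <- rda_fit(y, pred)$axis_variance_fraction
  pca_frac <- run_pca(y, n_axes = 2)$axis_variance_fraction
  expect_true(all(rda_frac <= pca_frac + 1e-12))
  expect_error(rda_fit(y, cbind(rep(1, n), pred[, 1])), "constant predictor")
})

test_that("RDA axis variance fractions agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(41)
  n <- 30
  pred <- cbind(lat = rnorm(n), lon = rnorm(n))
  y <- matrix(rnorm(n * 12), n, 12) + pred %*% matrix(rnorm(24), 2, 12)
  ours <- rda_fit(y, pred)
  ref <- vegan::rda(y ~ lat + lon, data = as.data.frame(pred))
  ref_frac <- ref$CCA$eig / ref$tot.chi
  expect_equal(unname(ours$axis_variance_fraction), unname(ref_frac),
    tolerance = 1e-8
  )
})
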