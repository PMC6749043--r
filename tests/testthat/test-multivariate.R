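test_that("PCA recovers rank structure and explained variance", {
  set.seed(21)
  # rank-1 data: one component carries all variance
  u <- rnorm(10); v <- rnorm(15)
  pca <- fit_pca(outer(u, v), n_components = 2)
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-9)
  # orthonormal loadings, non-increasing fractions
  X <- matrix(rnorm(12 * 8), 12, 8)
  full <- fit_pca(X, n_components = 8)
  expect_equal(crossprod(full$loadings), diag(8), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(full$explained_variance_fraction) <= 1e-12))
  # reconstruction residual matches the unexplained variance
  k <- 3
  pk <- fit_pca(X, n_components = k)
  Xc <- scale(X, scale = FALSE)
  recon <- pk$scores %*% t(pk$loadings)
  resid2 <- sum((Xc - recon)^2)
  expect_equal(resid2 / sum(Xc^2),
               1 - sum(pk$explained_variance_fraction), tolerance = 1e-9)
  expect_error(fit_pca(X, n_components = 12), "n_components")
})

test_that("groups with strong injected effects separate along PC1", {
  eff <- effect_table(table1, "SHR-N_vs_WKY-N")
  # amplify the printed effects to make the separation unambiguous
  eff$fold_change <- 1 + 3 * (eff$fold_change - 1)
  eff$fold_change[eff$fold_change <= 0.05] <- 0.05
  coh <- simulate_cohort(serum_library, eff, small_design(seed = 22))
  coh <- exclude_region(coh)
  sc <- scale_features(pqn_normalize(adaptive_bin(coh, 0.015))$matrix)
  pca <- fit_pca(sc, 2)
  g <- sc$sample_meta$group
  pc1 <- pca$scores[, 1]
  # silhouette along PC1 positive: centroid gap exceeds within-group spread
  gap <- abs(mean(pc1[g == "SHR-N"]) - mean(pc1[g == "WKY-N"]))
  spread <- max(tapply(pc1, g, sd))
  expect_gt(gap, spread)
})

test_that("OPLS-DA with no orthogonal components equals PLS1 (NIPALS oracle)", {
  set.seed(23)
  for (rep in 1:20) {
    X <- matrix(rnorm(12 * 30), 12, 30)
    cls <- factor(rep(c("A", "B"), each = 6))
    y <- ifelse(cls == "B", 1, -1)
    model <- fit_oplsda(X, cls, n_orthogonal = 0)
    oracle <- pls1_nipals_oracle(X, y)
    sgn <- sign(sum(model$predictive_weights * oracle$w))
    expect_equal(model$predictive_weights, sgn * oracle$w,
                 tolerance = 1e-8)
    expect_equal(model$predictive_scores, sgn * oracle$t,
                 tolerance = 1e-8)
  }
})

test_that("predictive and orthogonal scores are orthogonal and R2X partitions", {
  set.seed(24)
  X <- matrix(rnorm(20 * 40), 20, 40)
  cls <- factor(rep(c("A", "B"), each = 10))
  m <- fit_oplsda(X, cls, n_orthogonal = 2)
  for (a in seq_len(ncol(m$orthogonal_scores))) {
    expect_lt(abs(sum(m$predictive_scores * m$orthogonal_scores[, a])),
              1e-8)
  }
  # explained predictive + orthogonal + residual = total X variance
  recon <- tcrossprod(m$predictive_scores, m$predictive_loadings) +
    tcrossprod(m$orthogonal_scores, m$orthogonal_loadings)
  resid <- sum((X - recon)^2)
  expect_equal((sum(recon^2) + resid) / sum(X^2), 1, tolerance = 1e-6)
  expect_equal(m$r2x, sum(recon^2) / sum(X^2), tolerance = 1e-6)
  expect_true(m$r2x >= 0 && m$r2x <= 1)
  expect_true(m$r2y >= 0 && m$r2y <= 1)
})

test_that("orthogonal filtering absorbs a class-orthogonal confounder", {
  set.seed(25)
  n <- 20; p <- 30
  cls <- factor(rep(c("A", "B"), each = 10))
  signal <- outer(ifelse(cls == "B", 1, -1), rnorm(p, 0, 0.4))
  # batch shift hitting half the samples of each class
  batch <- rep(c(1, -1), times = 10)
  confound <- outer(batch, rnorm(p, 0, 2))
  X <- signal + confound + matrix(rnorm(n * p, 0, 0.3), n, p)
  m0 <- fit_oplsda(X, cls, n_orthogonal = 0)
  m1 <- fit_oplsda(X, cls, n_orthogonal = 1)
  expect_gte(m1$r2y, m0$r2y)
  # randomly permuted labels reduce r2y on effect-bearing data
  perm <- with(list(), {set.seed(26); sample(as.character(cls))})
  mp <- fit_oplsda(X, factor(perm), n_orthogonal = 1)
  expect_lt(mp$r2y, m1$r2y)
})

test_that("class handling is validated", {
  X <- matrix(rnorm(12 * 5), 12, 5)
  expect_error(fit_oplsda(X, factor(rep(c("A", "B", "C"), each = 4))),
               "exactly 2 classes")
  expect_error(fit_oplsda(X, factor(rep(c("A", "B"), c(10, 2)))),
               ">= 3 samples")
})

test_that("VIP scores satisfy their algebraic identities", {
  set.seed(27)
  X <- matrix(rnorm(16 * 25), 16, 25)
  cls <- factor(rep(c("A", "B"), each = 8))
  m <- fit_oplsda(X, cls, n_orthogonal = 1)
  expect_true(all(m$vip >= 0))
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  expect_equal(mean(compute_vip(m, "total")^2), 1, tolerance = 1e-8)
  # all features carrying identical contribution -> VIP all 1
  y <- ifelse(cls == "B", 1, -1)
  Xsym <- outer(y, rep(1, 10))
  msym <- fit_oplsda(Xsym, cls, n_orthogonal = 0)
  expect_equal(msym$vip, rep(1, 10), tolerance = 1e-9)
  # the feature carrying the whole class effect gets the max VIP
  Xone <- matrix(rnorm(16 * 25, 0, 0.2), 16, 25)
  Xone[, 7] <- y + rnorm(16, 0, 0.1)
  mone <- fit_oplsda(Xone, cls, n_orthogonal = 0)
  expect_equal(which.max(mone$vip), 7L)
  expect_error(compute_vip(list()), "fitted")
})

test_that("coefficient loadings pair covariance with bounded correlation", {
  set.seed(28)
  cls <- factor(rep(c("A", "B"), each = 8))
  y <- ifelse(cls == "B", 1, -1)
  X <- outer(y, rnorm(12)) + matrix(rnorm(16 * 12, 0, 0.05), 16, 12)
  m <- fit_oplsda(X, cls, n_orthogonal = 0)
  cl <- coefficient_loadings(m, X)
  expect_true(all(abs(cl$correlation) <= 1 + 1e-12))
  # covariance sign matches the group-mean contrast per feature
  contrast <- colMeans(X[cls == "B", ]) - colMeans(X[cls == "A", ])
  expect_equal(sign(cl$covariance), sign(contrast))
  # degenerate feature -> (0, 0) with warning
  X2 <- cbind(X, 5)
  m2 <- fit_oplsda(X2, cls, n_orthogonal = 0)
  expect_warning(cl2 <- coefficient_loadings(m2, X2), "zero-variance")
  expect_equal(unlist(cl2[13, ]), c(covariance = 0, correlation = 0))
  expect_error(coefficient_loadings(m, X2), "shape")
})

test_that("cross-validated Q2 separates signal from noise deterministically", {
  set.seed(29)
  cls <- factor(rep(c("A", "B"), each = 10))
  # pure noise: Q2 stays low
  null_q2 <- vapply(1:10, function(i) {
    X <- matrix(rnorm(20 * 30), 20, 30)
    cross_validate_q2(X, cls, n_orthogonal = 0, n_repeats = 3, seed = i)
  }, numeric(1))
  expect_lt(mean(null_q2), 0.2)
  # strong amplified effects: Q2 > 0.5
  eff <- effect_table(table1, "SHR-N_vs_WKY-N")
  eff$fold_change <- 1 + 3 * (eff$fold_change - 1)
  eff$fold_change[eff$fold_change <= 0.05] <- 0.05
  coh <- simulate_cohort(serum_library, eff,
                         small_design(noise_sd = 0.1, seed = 30))
  coh <- exclude_region(coh)
  sc <- scale_features(pqn_normalize(adaptive_bin(coh, 0.015))$matrix)
  q2 <- cross_validate_q2(sc, factor(sc$sample_meta$group),
                          n_orthogonal = 1, n_repeats = 7, seed = 31)
  expect_gt(q2, 0.5)
  # determinism under a fixed seed
  q2b <- cross_validate_q2(sc, factor(sc$sample_meta$group),
                           n_orthogonal = 1, n_repeats = 7, seed = 31)
  expect_identical(q2, q2b)
})

test_that("permutation test applies the add-one estimator and is seeded", {
  set.seed(32)
  cls <- factor(rep(c("A", "B"), each = 8))
  y <- ifelse(cls == "B", 1, -1)
  X <- outer(y, rnorm(20)) + matrix(rnorm(16 * 20, 0, 0.1), 16, 20)
  res <- permutation_test(X, cls, n_orthogonal = 0, n_permutations = 99,
                          seed = 33)
  expect_length(res$permuted_q2, 99)
  # the observed model dominates every permutation -> p at its floor
  expect_equal(res$p_value, 1 / 100)
  res2 <- permutation_test(X, cls, n_orthogonal = 0, n_permutations = 99,
                           seed = 33)
  expect_identical(res$permuted_q2, res2$permuted_q2)
  expect_error(permutation_test(X, cls, n_permutations = 0), "n_permutations")
})
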