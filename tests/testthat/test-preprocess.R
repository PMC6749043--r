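test_that("water-region exclusion removes exactly the interval", {
  des <- small_design(n_per_group = 3, ppm_grid = c(0.5, 9.0, 2000))
  coh <- simulate_cohort(serum_library, NULL, des)
  sp <- as_spectra(coh)[[1]]
  inside <- sum(sp$ppm >= 4.33 & sp$ppm <= 5.50)
  cut <- exclude_region(sp, 4.33, 5.50)
  expect_false(any(cut$ppm >= 4.33 & cut$ppm <= 5.50))
  expect_equal(length(cut$ppm), length(sp$ppm) - inside)
  expect_identical(cut$intensity,
                   sp$intensity[sp$ppm < 4.33 | sp$ppm > 5.50])
  # disjoint interval leaves the spectrum unchanged
  same <- exclude_region(sp, 100, 101)
  expect_identical(same$ppm, sp$ppm)
  # removing everything is an error
  expect_error(exclude_region(sp, 0, 10), "entire spectrum")
  expect_error(exclude_region(sp, 5, 4), "low < high")
})

test_that("flat spectra bin uniformly at the target width", {
  ppm <- seq(0.5, 7.5, length.out = 4000)
  flat <- lapply(1:3, function(i) {
    structure(list(ppm = ppm, intensity = rep(2, length(ppm)),
                   sample_id = paste0("s", i), group = "A"),
              class = "nmr_spectrum")
  })
  fm <- adaptive_bin(flat, target_width = 0.015)
  widths <- fm$feature_meta$right - fm$feature_meta$left
  expect_equal(mean(widths), 0.015, tolerance = 0.1)
  expect_lt(max(abs(widths - mean(widths))), 0.1 * 0.015)
  # every integral = constant x width
  expect_equal(fm$values[1, ], 2 * widths, tolerance = 1e-9,
               ignore_attr = TRUE)
  # bin count follows range / width arithmetic
  expect_equal(ncol(fm$values), round(7.0 / 0.015), tolerance = 0.1)
})

test_that("adaptive boundaries avoid peak apexes and partition the range", {
  des <- small_design(n_per_group = 3)
  coh <- simulate_cohort(serum_library, NULL, des)
  coh <- exclude_region(coh)
  fm <- adaptive_bin(coh, 0.015)
  # partition: consecutive bins share edges within each segment
  edges <- fm$feature_meta
  gaps <- edges$left[-1] - edges$right[-nrow(edges)]
  expect_true(all(gaps >= -1e-12))
  # only the excluded region may open a gap
  big_gap <- which(gaps > 1e-9)
  expect_lte(length(big_gap), 1L)
  if (length(big_gap)) {
    expect_lt(edges$right[big_gap], 4.34)
    expect_gt(edges$left[big_gap + 1], 5.49)
  }
  expect_equal(mean(edges$right - edges$left), 0.015, tolerance = 0.1)
  # no boundary within half a linewidth of an isolated singlet apex
  apex <- 2.37  # pyruvate, isolated within its bin
  interior <- edges$left[-1]
  expect_false(any(abs(interior - apex) < des$linewidth / 2))
  # mass preservation: bin integrals sum to the retained trapezoid integral
  total_bins <- rowSums(fm$values)
  total_direct <- vapply(as_spectra(coh), function(sp) {
    sum(diff(sp$ppm[sp$ppm <= 4.33]) *
          (sp$intensity[sp$ppm <= 4.33][-1] +
             sp$intensity[sp$ppm <= 4.33][-sum(sp$ppm <= 4.33)])) / 2 +
      sum(diff(sp$ppm[sp$ppm >= 5.5]) *
            (sp$intensity[sp$ppm >= 5.5][-1] +
               sp$intensity[sp$ppm >= 5.5][-sum(sp$ppm >= 5.5)])) / 2
  }, numeric(1))
  expect_equal(total_bins, total_direct, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(adaptive_bin(coh, -1), "target_width")
})

test_that("PQN collapses pure dilution and reports the factors", {
  set.seed(11)
  profile <- abs(rnorm(60)) + 0.5
  cvec <- exp(rnorm(10, 0, 0.25))
  fm <- as_binned(outer(cvec, profile))
  out <- pqn_normalize(fm)
  # all rows identical after normalization
  expect_lt(max(abs(sweep(out$matrix$values, 2,
                          out$matrix$values[1, ]))), 1e-9)
  # reported dilution factors proportional to the injected scalars
  ratio <- out$report$dilution / cvec
  expect_lt(max(abs(ratio - mean(ratio))), 1e-9)
  expect_gt(stats::cor(out$report$dilution, cvec), 0.99)
  expect_equal(out$matrix$stage, "normalized")
})

test_that("PQN is idempotent on its own output", {
  set.seed(12)
  base <- outer(exp(rnorm(8, 0, 0.3)), abs(rnorm(50)) + 0.3)
  noisy <- base * matrix(exp(rnorm(length(base), 0, 0.1)), nrow(base))
  p1 <- pqn_normalize(as_binned(noisy))
  again <- p1$matrix
  again$stage <- "binned"
  p2 <- pqn_normalize(again)
  rel <- abs(p2$matrix$values - p1$matrix$values) /
    (abs(p1$matrix$values) + 1e-12)
  expect_lt(max(rel), 0.01)
  # second-pass quotients are all ~1
  expect_lt(max(abs(p2$report$pqn_quotient - 1)), 0.02)
})

test_that("PQN reduces dilution-driven spread in synthetic cohorts", {
  eff <- effect_table(table1, "SHR-N_vs_WKY-N")
  des <- small_design(dilution_sd = 0.2, seed = 13)
  coh <- simulate_cohort(serum_library, eff, des)
  coh <- exclude_region(coh)
  fm <- adaptive_bin(coh, 0.015)
  out <- pqn_normalize(fm)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(rowSums(out$matrix$values)), cv(rowSums(fm$values)))
  expect_error(pqn_normalize(as_binned(matrix(0, 3, 4))), "s01")
})

test_that("pareto scaling centres columns and leaves variance = sd", {
  set.seed(14)
  X <- matrix(rnorm(8 * 6, mean = 5, sd = rep(c(1, 4), each = 24)), 8, 6)
  fm <- as_binned(X)
  fm$stage <- "normalized"
  pre_sd <- apply(X, 2, sd)
  sc <- scale_features(fm)
  expect_lt(max(abs(colMeans(sc$values))), 1e-12)
  expect_equal(apply(sc$values, 2, var), pre_sd, tolerance = 1e-9,
               ignore_attr = TRUE)
  # constant column -> zeros plus a warning, indices preserved
  X2 <- cbind(X, 3)
  fm2 <- as_binned(X2); fm2$stage <- "normalized"
  expect_warning(sc2 <- scale_features(fm2), "constant")
  expect_true(all(sc2$values[, 7] == 0))
  expect_equal(ncol(sc2$values), 7L)
  one <- as_binned(X[1, , drop = FALSE]); one$stage <- "normalized"
  expect_error(scale_features(one), "2 samples")
  expect_error(scale_features(as_binned(X)), "normalized")
})

test_that("the preprocessing chain is deterministic", {
  eff <- effect_table(table1, "SHR-N_vs_WKY-N")
  run <- function() {
    coh <- simulate_cohort(serum_library, eff,
                           small_design(n_per_group = 3, seed = 5))
    coh <- exclude_region(coh)
    scale_features(pqn_normalize(adaptive_bin(coh, 0.015))$matrix)$values
  }
  expect_identical(run(), run())
})
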