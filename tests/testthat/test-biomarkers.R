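test_that("metabolite integrals are linear and windows independent", {
  lib <- data.frame(metabolite = c("a", "b"),
                    shift = c(2.0, 3.0), multiplicity = "s",
                    relative_area = 1, base_level = 1,
                    integrate = 1L)
  class(lib) <- c("resonance_library", "data.frame")
  des <- small_design(noise_sd = 0, baseline_amplitude = 0,
                      dilution_sd = 0, bio_cv = 0, n_per_group = 3)
  sp1 <- simulate_spectrum(lib, c(a = 1, b = 1), des)
  sp2 <- simulate_spectrum(lib, c(a = 2, b = 1), des)
  set1 <- adaptive_bin(list(sp1, sp1), 0.015)
  ints1 <- integrate_metabolites(set1, lib)
  set2 <- adaptive_bin(list(sp2, sp2), 0.015)
  ints2 <- integrate_metabolites(set2, lib)
  # doubling metabolite a doubles its integral ...
  expect_equal(unname(ints2$values[1, "a"] / ints1$values[1, "a"]), 2,
               tolerance = 0.01)
  # ... and leaves the separated metabolite b fixed within 1%
  expect_equal(unname(ints2$values[1, "b"] / ints1$values[1, "b"]), 1,
               tolerance = 0.01)
})

test_that("integration windows inside the excluded region error", {
  lib <- data.frame(metabolite = "water_region", shift = 4.9,
                    multiplicity = "s", relative_area = 1, base_level = 1,
                    integrate = 1L)
  class(lib) <- c("resonance_library", "data.frame")
  coh <- simulate_cohort(serum_library, NULL,
                         small_design(n_per_group = 3))
  coh <- exclude_region(coh)
  expect_error(integrate_metabolites(coh, lib), "excluded or uncovered")
  fm <- adaptive_bin(coh, 0.015)
  expect_error(integrate_metabolites(fm, lib), "excluded or uncovered")
  # overlapping windows between metabolites are flagged, not fatal
  lib2 <- data.frame(metabolite = c("x", "y"), shift = c(2.00, 2.01),
                     multiplicity = "s", relative_area = 1, base_level = 1,
                     integrate = 1L)
  class(lib2) <- c("resonance_library", "data.frame")
  ints <- integrate_metabolites(fm, lib2)
  expect_false(is.null(attr(ints, "overlaps")))
})

test_that("t-tests report raw and BH-adjusted p with the BH ordering", {
  eff <- effect_table(table1, "SHR-N_vs_WKY-N")
  coh <- simulate_cohort(serum_library, eff, small_design(seed = 41))
  coh <- exclude_region(coh)
  ints <- integrate_metabolites(pqn_normalize(adaptive_bin(coh, 0.015))$matrix,
                                serum_library)
  stats <- univariate_tests(ints, c("WKY-N", "SHR-N"))
  expect_true(all(stats$p_adjusted >= stats$p_raw - 1e-15))
  expect_true(all(stats$p_raw >= 0 & stats$p_raw <= 1))
  # identical groups: no systematic significance
  null_coh <- simulate_cohort(serum_library, NULL, small_design(seed = 42))
  null_coh <- exclude_region(null_coh)
  null_ints <- integrate_metabolites(
    pqn_normalize(adaptive_bin(null_coh, 0.015))$matrix, serum_library)
  null_stats <- univariate_tests(null_ints, c("WKY-N", "SHR-N"))
  expect_lt(mean(null_stats$p_raw < 0.05), 0.25)
  expect_error(univariate_tests(ints, c("WKY-N", "nope")), ">= 3 samples")
})

test_that("fold change is the case-over-reference mean ratio", {
  X <- rbind(matrix(2, 3, 2), matrix(3, 3, 2))
  colnames(X) <- c("m1", "m2")
  fm <- feature_matrix(X, data.frame(metabolite = c("m1", "m2"),
                                     left = 1:2, right = 2:3,
                                     center = 1.5:2.5),
                       data.frame(sample_id = sprintf("s%d", 1:6),
                                  group = rep(c("ref", "case"), each = 3)),
                       stage = "integrals")
  fc <- fold_change(fm, c("ref", "case"))
  expect_equal(fc$fc, c(1.5, 1.5))
  # case = reference -> fc = 1
  fc1 <- fold_change(fm, c("ref", "ref"))
  expect_equal(fc1$fc, c(1, 1))
  fm$values[1, 1] <- -10
  expect_error(fold_change(fm, c("ref", "case")), "non-positive")
})

test_that("selection on the printed tables reproduces the published counts", {
  s1 <- select_biomarkers(table1, 0.05, 1.0)
  s2 <- select_biomarkers(table2, 0.05, 1.0)
  expect_equal(nrow(s1$selected), 28L)
  expect_equal(nrow(s2$selected), 20L)
  # impossible thresholds empty the selection
  none <- select_biomarkers(table1, p_threshold = 0, vip_threshold = Inf)
  expect_equal(nrow(none$selected), 0L)
  broken <- table1
  broken$records$vip <- NULL
  expect_error(select_biomarkers(broken), "VIP")
})

test_that("the reversal rule isolates the 13 published biomarkers", {
  s1 <- select_biomarkers(table1)
  s2 <- select_biomarkers(table2)
  shared <- shared_reversed(s1, s2)
  expect_setequal(
    normalize_metabolite(shared$metabolites),
    normalize_metabolite(c("glucose", "LDL/VLDL", "alanine", "asparagine",
                           "glutamate", "glutamine", "lactate", "methionine",
                           "myo-Inositol", "serine", "threonine", "tyrosine",
                           "valine")))
  # brute-force set oracle for the plain intersection
  oracle_intersection <- intersect(
    normalize_metabolite(s1$selected$metabolite),
    normalize_metabolite(s2$selected$metabolite))
  expect_equal(length(oracle_intersection), 17L)
  expect_setequal(normalize_metabolite(shared$intersection),
                  oracle_intersection)
  # reversal set within intersection within each selected set
  expect_true(all(normalize_metabolite(shared$metabolites) %in%
                    normalize_metabolite(shared$intersection)))
  expect_true(all(oracle_intersection %in%
                    normalize_metabolite(s1$selected$metabolite)))
  # the four same-direction shared metabolites are excluded by the rule
  dropped <- setdiff(normalize_metabolite(shared$intersection),
                     normalize_metabolite(shared$metabolites))
  expect_setequal(dropped, normalize_metabolite(
    c("Isoleucine", "Lysine", "pyruvate", "N,N-dimethylglycine")))
})

test_that("disjoint selections give an empty reversal set", {
  half1 <- table1; half1$records <- table1$records[1:10, ]
  half2 <- table1; half2$records <- table1$records[15:25, ]
  half2$contrast <- "other"
  s1 <- select_biomarkers(half1)
  s2 <- select_biomarkers(half2)
  shared <- shared_reversed(s1, s2)
  expect_length(shared$metabolites, 0)
  expect_length(shared$intersection, 0)
  expect_error(shared_reversed(half1, s2), "select_biomarkers")
})

test_that("injected Table-1 effects are recovered end to end", {
  # sensitivity for clear effects and specificity for null metabolites,
  # averaged over repeated cohorts at the study's n = 10 per group
  seeds <- 1:20
  eff <- effect_table(table1, "SHR-N_vs_WKY-N")
  key <- normalize_metabolite(eff$metabolite)
  strong <- eff$metabolite[abs(eff$fold_change - 1) >= 0.2]
  lib_mets <- unique(serum_library$metabolite)
  nulls <- lib_mets[!normalize_metabolite(lib_mets) %in% key]
  sens <- numeric(0); fpr <- numeric(0)
  for (s in seeds) {
    coh <- simulate_cohort(serum_library, eff,
                           cohort_design(groups = c("WKY-N", "SHR-N"),
                                         seed = s))
    coh <- exclude_region(coh)
    pq <- pqn_normalize(adaptive_bin(coh, 0.015))$matrix
    ints <- integrate_metabolites(pq, serum_library)
    cls <- factor(ints$sample_meta$group, levels = c("WKY-N", "SHR-N"))
    bin_model <- fit_oplsda(scale_features(pq), cls, n_orthogonal = 1)
    vip <- metabolite_vip(bin_model, pq, serum_library)
    tab <- biomarker_table(univariate_tests(ints, c("WKY-N", "SHR-N")),
                           fold_change(ints, c("WKY-N", "SHR-N")),
                           vip, "SHR-N_vs_WKY-N")
    sel <- select_biomarkers(tab)$selected$metabolite
    sens <- c(sens, mean(normalize_metabolite(strong) %in%
                           normalize_metabolite(sel)))
    fpr <- c(fpr, mean(normalize_metabolite(nulls) %in%
                         normalize_metabolite(sel)))
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fpr), 0.1)
})
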