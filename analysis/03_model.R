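#!/usr/bin/env Rscript
# Stage 3: multivariate modelling.
#
# PCA for an unsupervised overview, then a two-class OPLS-DA per contrast
# (one predictive + one orthogonal component) validated by repeated
# twofold cross-validated Q2 and a permutation test.  499 permutations
# keep this driver interactive; the package default (and the study's
# setting) is 2000, available via n_permutations below.  Writes scores,
# VIP vectors, coefficient loadings and a model summary under results/.

suppressPackageStartupMessages(library(nmrmetab))

n_permutations <- 499
summary_rows <- list()

read_features <- function(nm) {
  path <- file.path("results", paste0("features_", nm, ".csv"))
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- utils::read.csv(paste0(path, ".meta.csv"))
  vals <- as.matrix(df[, -(1:2)])
  feature_matrix(vals, meta[, c("left", "right", "center")],
                 df[, 1:2], stage = "normalized")
}

for (nm in c("disease", "treatment")) {
  fmn <- read_features(nm)
  fm <- scale_features(fmn)
  groups <- unique(fm$sample_meta$group)
  classes <- factor(fm$sample_meta$group, levels = groups)

  pca <- fit_pca(fm, 2)
  message(sprintf("%s PCA: PC1 %.1f%%, PC2 %.1f%%", nm,
                  100 * pca$explained_variance_fraction[1],
                  100 * pca$explained_variance_fraction[2]))

  model <- fit_oplsda(fm, classes, n_orthogonal = 1)
  model$q2 <- cross_validate_q2(fm, classes, n_orthogonal = 1,
                                n_repeats = 7, seed = 11)
  perm <- permutation_test(fm, classes, n_orthogonal = 1,
                           n_permutations = n_permutations, seed = 12)
  message(sprintf(
    "%s OPLS-DA (%s vs %s): R2X %.2f, R2Y %.2f, Q2 %.2f, perm p %.4f",
    nm, groups[2], groups[1], model$r2x, model$r2y, model$q2, perm$p_value))

  utils::write.csv(
    data.frame(fm$sample_meta,
               t_predictive = model$predictive_scores,
               t_orthogonal = model$orthogonal_scores[, 1],
               pc1 = pca$scores[, 1], pc2 = pca$scores[, 2]),
    file.path("results", paste0("scores_", nm, ".csv")), row.names = FALSE)
  cl <- coefficient_loadings(model, fm)
  utils::write.csv(
    cbind(fm$feature_meta, vip = model$vip, cl),
    file.path("results", paste0("loadings_", nm, ".csv")),
    row.names = FALSE)
  summary_rows[[nm]] <- data.frame(
    contrast = paste(groups[2], "vs", groups[1]),
    r2x = model$r2x, r2y = model$r2y, q2 = model$q2,
    permutation_p = perm$p_value, n_permutations = n_permutations)
}
utils::write.csv(do.call(rbind, summary_rows),
                 "results/model_summary.csv", row.names = FALSE)
message("wrote results/model_summary.csv")
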