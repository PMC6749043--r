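#!/usr/bin/env Rscript
# Stage 4: biomarker selection.
#
# Integrates each metabolite's marker window from the normalized feature
# matrices, runs Student t-tests with Benjamini-Hochberg correction,
# attaches peak-level VIP from the bin OPLS-DA model, selects biomarkers at
# p < 0.05 and VIP > 1 per contrast, and applies the reversal rule
# (fold change crossing 1 in opposite directions) to the two selections.

suppressPackageStartupMessages(library(nmrmetab))

lib <- load_resonance_library()
contrast_groups <- list(disease = c("WKY-N", "SHR-N"),
                        treatment = c("SHR-N", "SHR-H"))

read_features <- function(nm) {
  path <- file.path("results", paste0("features_", nm, ".csv"))
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- utils::read.csv(paste0(path, ".meta.csv"))
  feature_matrix(as.matrix(df[, -(1:2)]),
                 meta[, c("left", "right", "center")],
                 df[, 1:2], stage = "normalized")
}

tables <- list()
for (nm in names(contrast_groups)) {
  groups <- contrast_groups[[nm]]
  fmn <- read_features(nm)
  model <- fit_oplsda(scale_features(fmn),
                      factor(fmn$sample_meta$group, levels = groups),
                      n_orthogonal = 1)
  ints <- integrate_metabolites(fmn, lib)
  tab <- biomarker_table(univariate_tests(ints, groups),
                         fold_change(ints, groups),
                         metabolite_vip(model, fmn, lib),
                         paste(groups[2], groups[1], sep = "_vs_"))
  tables[[nm]] <- select_biomarkers(tab, p_threshold = 0.05,
                                    vip_threshold = 1.0)
  utils::write.csv(
    tables[[nm]]$records[, c("metabolite", "p_raw", "p_adjusted", "fc",
                             "vip")],
    file.path("results", paste0("biomarkers_", nm, ".csv")),
    row.names = FALSE)
  message(sprintf("%s: %d of %d metabolites selected (p < 0.05, VIP > 1)",
                  nm, nrow(tables[[nm]]$selected), nrow(tab$records)))
}

shared <- shared_reversed(tables$disease, tables$treatment)
message(sprintf("shared in both contrasts: %d; reversed by treatment: %d",
                length(shared$intersection), length(shared$metabolites)))
message("reversed set: ", paste(sort(shared$metabolites), collapse = ", "))
utils::write.csv(data.frame(metabolite = shared$metabolites),
                 "results/shared_biomarkers.csv", row.names = FALSE)
message("wrote results/shared_biomarkers.csv")
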