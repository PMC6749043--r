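#!/usr/bin/env Rscript
# Stage 1: simulate the serum cohorts.
#
# Builds two synthetic 1H-NMR cohorts (n = 10 rats per group) whose
# group-mean metabolite ratios follow the transcribed printed tables:
# the disease contrast (SHR-N vs WKY-N) and the treatment contrast
# (SHR-H vs SHR-N).  Spectra are written as wide CSV (rows = samples,
# columns = ppm grid) with sample metadata sidecars under results/.

suppressPackageStartupMessages(library(nmrmetab))
dir.create("results", showWarnings = FALSE)

lib <- load_resonance_library()
table1 <- load_biomarker_table(nmrmetab_extdata("table1_wky_vs_shr.csv"),
                               "SHR-N_vs_WKY-N")
table2 <- load_biomarker_table(nmrmetab_extdata("table2_shr_vs_shrh.csv"),
                               "SHR-H_vs_SHR-N")

cohorts <- list(
  disease = list(effects = effect_table(table1, "SHR-N_vs_WKY-N"),
                 groups = c("WKY-N", "SHR-N")),
  treatment = list(effects = effect_table(table2, "SHR-H_vs_SHR-N"),
                   groups = c("SHR-N", "SHR-H")))

for (nm in names(cohorts)) {
  ct <- cohorts[[nm]]
  des <- cohort_design(groups = ct$groups, reference_group = ct$groups[1],
                       seed = 1)
  coh <- simulate_cohort(lib, ct$effects, des)
  write_spectrum_set(coh,
                     file.path("results", paste0("spectra_", nm, ".csv")),
                     file.path("results", paste0("samples_", nm, ".csv")))
  message(sprintf("%s cohort: %d spectra x %d points, %d metabolites with ",
                  nm, nrow(coh$intensities), length(coh$ppm),
                  nrow(ct$effects)),
          "injected effects")
}
message("wrote results/spectra_{disease,treatment}.csv")
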