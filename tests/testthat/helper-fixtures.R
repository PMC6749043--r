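# Shared test fixtures, built in code.

serum_library <- load_resonance_library()

table1 <- load_biomarker_table(nmrmetab_extdata("table1_wky_vs_shr.csv"),
                               "SHR-N_vs_WKY-N")
table2 <- load_biomarker_table(nmrmetab_extdata("table2_shr_vs_shrh.csv"),
                               "SHR-H_vs_SHR-N")

# compact two-group design for fast tests (fewer grid points than the
# production default, same physics)
small_design <- function(...) {
  args <- utils::modifyList(
    list(groups = c("WKY-N", "SHR-N"), n_per_group = 5,
         ppm_grid = c(0.5, 9.0, 4096), seed = 7),
    list(...))
  do.call(cohort_design, args)
}

# noiseless single-singlet library for forward-model oracles
singlet_library <- function(shift = 2.37, base_level = 1) {
  lib <- data.frame(metabolite = "probe", shift = shift,
                    multiplicity = "s", relative_area = 1,
                    base_level = base_level, integrate = 1L)
  class(lib) <- c("resonance_library", "data.frame")
  lib
}

# trapezoidal integral over a window of a spectrum
trapz_window <- function(sp, lo, hi) {
  idx <- which(sp$ppm >= lo & sp$ppm <= hi)
  x <- sp$ppm[idx]; y <- sp$intensity[idx]
  sum(diff(x) * (y[-1] + y[-length(y)])) / 2
}

# a plain binned feature matrix from a numeric matrix
as_binned <- function(X, group = rep("A", nrow(X))) {
  p <- ncol(X)
  feature_matrix(X,
                 data.frame(left = seq(0, p - 1), right = seq(1, p),
                            center = seq(0.5, p - 0.5)),
                 data.frame(sample_id = sprintf("s%02d", seq_len(nrow(X))),
                            group = group, stringsAsFactors = FALSE),
                 stage = "binned")
}
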