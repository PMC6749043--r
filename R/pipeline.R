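# End-to-end orchestration: simulate -> preprocess -> model -> biomarkers
# -> pathways, with a validated configuration, per-stage derived seeds and
# a reproducibility manifest.

pipeline_defaults <- function() {
  list(
    exclusion = c(4.33, 5.50),
    bin_width = 0.015,
    pqn_reference = "all",
    scaling = "pareto",
    n_orthogonal = 1,
    cv_repeats = 7,
    n_permutations = 2000,
    p_threshold = 0.05,
    vip_threshold = 1.0,
    impact_threshold = 0.1,
    half_window = 0.012,
    groups = c("WKY-N", "SHR-N", "SHR-H"),
    n_per_group = 10,
    dilution_sd = 0.1,
    noise_sd = 0.3,
    baseline_amplitude = 2,
    linewidth = 0.002,
    ppm_points = 16384,
    bio_cv = 0.1,
    seed = 1
  )
}

#' Validate a pipeline configuration
#'
#' Applies the study defaults (water exclusion 4.33-5.50 ppm, 0.015 ppm
#' bins, PQN, pareto scaling, 2000 permutations, p < 0.05, VIP > 1, impact
#' > 0.1), overlays a YAML file and/or an override list, rejects unknown
#' keys and reports all range violations at once.
#'
#' @param path optional YAML config file (empty or NULL means pure
#'   defaults).
#' @param overrides optional named list applied after the file.
#' @return validated configuration list of class \code{pipeline_config}.
#' @export
validate_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  user <- list()
  if (!is.null(path)) {
    loaded <- yaml::read_yaml(path)
    if (!is.null(loaded)) user <- loaded
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(cfg, user)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(length(cfg$exclusion) == 2 && cfg$exclusion[1] < cfg$exclusion[2],
      "exclusion: must be c(low, high) with low < high")
  chk(is.numeric(cfg$bin_width) && cfg$bin_width > 0,
      "bin_width: must be > 0")
  chk(cfg$n_orthogonal >= 0, "n_orthogonal: must be >= 0")
  chk(cfg$cv_repeats >= 1, "cv_repeats: must be >= 1")
  chk(cfg$n_permutations >= 1, "n_permutations: must be >= 1")
  chk(cfg$p_threshold > 0 && cfg$p_threshold <= 1,
      "p_threshold: must be in (0, 1]")
  chk(cfg$vip_threshold >= 0, "vip_threshold: must be >= 0")
  chk(cfg$n_per_group >= 3, "n_per_group: must be >= 3")
  chk(cfg$ppm_points >= 1000, "ppm_points: must be >= 1000")
  chk(length(cfg$groups) >= 2, "groups: need at least 2 group labels")
  chk(identical(cfg$scaling, "pareto"), "scaling: only 'pareto' supported")
  if (length(problems)) {
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort from the packaged printed-table effect fixtures,
#' preprocesses (exclusion, adaptive binning, PQN, pareto scaling), fits
#' OPLS-DA per contrast with cross-validated Q2 and permutation p,
#' integrates metabolites and selects biomarkers, applies the reversal
#' rule, and screens pathways.  All primary outputs are written as CSV
#' under \code{out_dir}, and a manifest (config echo, per-file checksums,
#' seed, timestamps) is written atomically at the end; identical config and
#' seed give identical checksums.
#'
#' @param config a \code{pipeline_config} (see \code{\link{validate_config}}).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config = validate_config(), out_dir = "results") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- character(0)
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  # --- synth ----------------------------------------------------------
  library <- load_resonance_library()
  t1 <- load_biomarker_table(nmrmetab_extdata("table1_wky_vs_shr.csv"),
                             "SHR-N_vs_WKY-N")
  t2 <- load_biomarker_table(nmrmetab_extdata("table2_shr_vs_shrh.csv"),
                             "SHR-H_vs_SHR-N")
  effects <- rbind(effect_table(t1, "SHR-N_vs_WKY-N"),
                   effect_table(t2, "SHR-H_vs_SHR-N"))
  class(effects) <- c("effect_table", "data.frame")
  design <- cohort_design(groups = config$groups,
                          n_per_group = config$n_per_group,
                          dilution_sd = config$dilution_sd,
                          noise_sd = config$noise_sd,
                          baseline_amplitude = config$baseline_amplitude,
                          linewidth = config$linewidth,
                          ppm_grid = c(0.5, 9.0, config$ppm_points),
                          bio_cv = config$bio_cv,
                          reference_group = config$groups[1],
                          seed = stage_seed(config$seed, "synth"))
  cohort <- simulate_cohort(library, effects, design)
  log_stage("synth", sprintf("%d spectra, %d points",
                             nrow(cohort$intensities), length(cohort$ppm)))

  # --- preprocess -----------------------------------------------------
  cohort <- exclude_region(cohort, config$exclusion[1], config$exclusion[2])
  binned <- adaptive_bin(cohort, config$bin_width)
  pqn <- pqn_normalize(binned, config$pqn_reference)
  scaled <- scale_features(pqn$matrix)
  f_matrix <- file.path(out_dir, "feature_matrix_normalized.csv")
  write_feature_matrix(pqn$matrix, f_matrix)
  files <- c(files, f_matrix, paste0(f_matrix, ".meta.csv"))
  log_stage("preprocess", sprintf("%d bins (mean width %.4f ppm)",
                                  ncol(binned$values),
                                  mean(binned$feature_meta$right -
                                       binned$feature_meta$left)))

  # --- model + biomarkers per contrast -------------------------------
  contrasts <- list(c("WKY-N", "SHR-N"), c("SHR-N", "SHR-H"))
  contrasts <- Filter(function(p) all(p %in% config$groups), contrasts)
  integrals <- integrate_metabolites(pqn$matrix, library,
                                     config$half_window)
  tables <- list()
  model_rows <- list()
  for (ct in contrasts) {
    lab <- paste(ct[2], ct[1], sep = "_vs_")
    sel <- binned$sample_meta$group %in% ct
    sub_norm <- feature_matrix(
      pqn$matrix$values[sel, , drop = FALSE], pqn$matrix$feature_meta,
      pqn$matrix$sample_meta[sel, , drop = FALSE], stage = "normalized")
    sub_scaled <- scale_features(sub_norm)
    classes <- factor(binned$sample_meta$group[sel], levels = ct)
    model <- fit_oplsda(sub_scaled, classes, config$n_orthogonal)
    model$q2 <- cross_validate_q2(sub_scaled, classes, config$n_orthogonal,
                                  config$cv_repeats,
                                  seed = stage_seed(config$seed, lab))
    perm <- permutation_test(sub_scaled, classes, config$n_orthogonal,
                             config$n_permutations,
                             seed = stage_seed(config$seed,
                                               paste0("perm_", lab)))
    model_rows[[lab]] <- data.frame(
      contrast = lab, r2x = model$r2x, r2y = model$r2y, q2 = model$q2,
      permutation_p = perm$p_value, stringsAsFactors = FALSE)
    log_stage("model", sprintf("%s: R2X %.3f R2Y %.3f Q2 %.3f p %.4g",
                               lab, model$r2x, model$r2y, model$q2,
                               perm$p_value))

    sub_int <- feature_matrix(
      integrals$values[sel, , drop = FALSE], integrals$feature_meta,
      integrals$sample_meta[sel, , drop = FALSE], stage = "integrals")
    vip <- metabolite_vip(model, pqn$matrix, library, config$half_window)
    tab <- biomarker_table(univariate_tests(sub_int, ct),
                           fold_change(sub_int, ct), vip, lab)
    tables[[lab]] <- select_biomarkers(tab, config$p_threshold,
                                       config$vip_threshold)
    f_tab <- file.path(out_dir, paste0("biomarkers_", lab, ".csv"))
    utils::write.csv(
      tables[[lab]]$records[, c("metabolite", "p_raw", "p_adjusted",
                                "fc", "vip")],
      f_tab, row.names = FALSE)
    files <- c(files, f_tab)
  }
  f_models <- file.path(out_dir, "model_summary.csv")
  utils::write.csv(do.call(rbind, model_rows), f_models, row.names = FALSE)
  files <- c(files, f_models)

  # --- shared biomarkers + pathways ----------------------------------
  manifest_extra <- list()
  if (length(tables) == 2) {
    shared <- shared_reversed(tables[[1]], tables[[2]])
    f_shared <- file.path(out_dir, "shared_biomarkers.csv")
    utils::write.csv(data.frame(metabolite = shared$metabolites),
                     f_shared, row.names = FALSE)
    files <- c(files, f_shared)
    log_stage("biomarkers", sprintf("%d reversed of %d shared",
                                    length(shared$metabolites),
                                    length(shared$intersection)))
    compounds <- suppressWarnings(map_to_compounds(shared$metabolites))
    pw <- load_pathways()
    res <- pathway_results(compounds, pw)
    screened <- screen_pathways(res, config$impact_threshold)
    f_pw <- file.path(out_dir, "pathway_results.csv")
    utils::write.csv(res, f_pw, row.names = FALSE)
    f_scr <- file.path(out_dir, "pathways_screened.csv")
    utils::write.csv(screened, f_scr, row.names = FALSE)
    files <- c(files, f_pw, f_scr)
    net <- build_metabolite_protein_network(shared$metabolites)
    f_net <- file.path(out_dir, "metabolite_protein_edges.csv")
    utils::write.csv(net$edges, f_net, row.names = FALSE)
    files <- c(files, f_net)
    log_stage("pathways", sprintf("%d screened of %d pathways",
                                  nrow(screened), nrow(res)))
    manifest_extra$shared_biomarkers <- shared$metabolites
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nmrmetab")),
    config = unclass(config),
    seed = config$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  manifest <- c(manifest, manifest_extra)
  f_manifest <- file.path(out_dir, "manifest.json")
  tmp <- paste0(f_manifest, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, f_manifest)
  invisible(manifest)
}
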