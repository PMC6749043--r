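# Univariate biomarker statistics and selection.
#
# Metabolite-level integrals are tested per contrast with a two-sample
# Student t-test, corrected across metabolites by Benjamini-Hochberg, and
# combined with OPLS-DA VIP scores: a metabolite is selected when raw
# p < 0.05 and VIP > 1.  Candidates significant in both the disease and the
# treatment contrast whose fold change crosses 1 in opposite directions
# (treatment-driven reversal) form the potential-biomarker set.

#' Load a transcribed biomarker table
#'
#' Reads a printed biomarker table fixture (metabolite, chemical shifts
#' with multiplicities, p, VIP, FC) into a \code{biomarker_table}.  Shifts
#' are parsed from the compact \code{"0.94(t);1.01(d)"} notation.
#'
#' @param path CSV fixture with columns \code{metabolite}, \code{shifts},
#'   \code{p}, \code{vip}, \code{fc}.
#' @param contrast label of the form \code{"CASE_vs_REFERENCE"}.
#' @return list of class \code{biomarker_table}: \code{contrast},
#'   \code{records} (with parsed \code{shift_list}), \code{selection}.
#' @export
load_biomarker_table <- function(path, contrast) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("metabolite", "shifts", "p", "vip", "fc")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("biomarker table missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(normalize_metabolite(df$metabolite))) {
    stop("duplicate metabolite names in biomarker table", call. = FALSE)
  }
  shift_list <- lapply(df$shifts, parse_shift_notation)
  records <- data.frame(metabolite = df$metabolite, shifts = df$shifts,
                        p_raw = df$p, vip = df$vip, fc = df$fc,
                        stringsAsFactors = FALSE)
  records$shift_list <- shift_list
  structure(list(contrast = contrast, records = records,
                 selection = NULL),
            class = "biomarker_table")
}

# "0.94(t);1.01(d)" -> data.frame(shift, multiplicity)
parse_shift_notation <- function(s) {
  parts <- trimws(strsplit(s, ";|,(?=[0-9])", perl = TRUE)[[1]])
  m <- regmatches(parts, regexec("^([0-9.]+)\\(([a-z]+)\\)$", parts))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("cannot parse chemical shift entry '", parts[bad][1], "'",
         call. = FALSE)
  }
  data.frame(shift = as.numeric(vapply(m, `[`, character(1), 2)),
             multiplicity = vapply(m, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Integrate metabolite signals per sample
#'
#' Integrates intensity over \code{[integration_shift - half_window,
#' integration_shift + half_window]} for every metabolite, either directly
#' from spectra (trapezoidal rule) or from a binned/normalized feature
#' matrix (bins weighted by fractional overlap with the window).  The
#' integration shift is the resonance flagged in the library (first listed
#' by default).  Windows of different metabolites that overlap are reported
#' in the \code{"overlaps"} attribute; a window inside the excluded region
#' is an error.
#'
#' @param x an \code{nmr_spectrum_set} or a \code{feature_matrix}.
#' @param library a \code{resonance_library}.
#' @param half_window half-width of the integration window (ppm).
#' @return a \code{feature_matrix} (stage \code{"integrals"}) with one
#'   column per metabolite.
#' @export
integrate_metabolites <- function(x, library, half_window = 0.012) {
  stopifnot(inherits(library, "resonance_library"))
  targets <- library[library$integrate == 1, , drop = FALSE]
  lo <- targets$shift - half_window
  hi <- targets$shift + half_window
  # flag overlapping windows between metabolites
  ord <- order(lo)
  overl <- which(hi[ord][-length(ord)] > lo[ord][-1])
  overlaps <- if (length(overl)) {
    data.frame(a = targets$metabolite[ord][overl],
               b = targets$metabolite[ord][overl + 1])
  } else NULL
  if (inherits(x, "nmr_spectrum_set")) {
    ppm <- x$ppm
    step <- stats::median(diff(ppm))
    vals <- matrix(0, nrow(x$intensities), nrow(targets),
                   dimnames = list(NULL, targets$metabolite))
    for (j in seq_len(nrow(targets))) {
      idx <- which(ppm >= lo[j] & ppm <= hi[j])
      covered <- length(idx) >= 2 &&
        max(diff(ppm[idx])) <= 3 * step &&
        (ppm[idx[1]] - lo[j]) <= 3 * step &&
        (hi[j] - ppm[idx[length(idx)]]) <= 3 * step
      if (!covered) {
        stop("integration window for '", targets$metabolite[j],
             "' [", lo[j], ", ", hi[j],
             "] falls in an excluded or uncovered region", call. = FALSE)
      }
      w <- diff(ppm[idx])
      seg <- x$intensities[, idx, drop = FALSE]
      vals[, j] <- as.vector((seg[, -length(idx), drop = FALSE] +
                              seg[, -1, drop = FALSE]) %*% w) / 2
    }
    sm <- x$sample_meta[, c("sample_id", "group")]
  } else if (inherits(x, "feature_matrix")) {
    fmeta <- x$feature_meta
    vals <- matrix(0, nrow(x$values), nrow(targets),
                   dimnames = list(NULL, targets$metabolite))
    for (j in seq_len(nrow(targets))) {
      ov_left <- pmax(fmeta$left, lo[j])
      ov_right <- pmin(fmeta$right, hi[j])
      frac <- pmax(0, ov_right - ov_left) / (fmeta$right - fmeta$left)
      if (sum(frac * (fmeta$right - fmeta$left)) <
          0.5 * (hi[j] - lo[j])) {
        stop("integration window for '", targets$metabolite[j],
             "' [", lo[j], ", ", hi[j],
             "] falls in an excluded or uncovered region", call. = FALSE)
      }
      vals[, j] <- as.vector(x$values %*% frac)
    }
    sm <- x$sample_meta
  } else {
    stop("x must be an nmr_spectrum_set or feature_matrix", call. = FALSE)
  }
  out <- feature_matrix(vals,
                        feature_meta = data.frame(
                          metabolite = targets$metabolite,
                          left = lo, right = hi,
                          center = targets$shift),
                        sample_meta = sm, stage = "integrals")
  attr(out, "overlaps") <- overlaps
  out
}

#' Metabolite-level VIP from a bin-level model
#'
#' VIP scores are computed over all spectral bins of the OPLS-DA model and
#' read off per metabolite as the maximum VIP among bins overlapping its
#' integration window.  Scoring peaks rather than metabolite integrals
#' keeps the VIP > 1 convention meaningful: with hundreds of bins the mean
#' squared VIP of 1 sits among baseline bins, so influential peak bins
#' stand out.
#'
#' @param model an \code{oplsda_model} fitted on a binned feature matrix.
#' @param fm the binned/normalized \code{feature_matrix} the model was
#'   fitted on (provides bin edges).
#' @param library a \code{resonance_library}.
#' @param half_window integration half-width in ppm.
#' @return named numeric vector of VIP scores, one per metabolite.
#' @export
metabolite_vip <- function(model, fm, library, half_window = 0.012) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(library, "resonance_library"))
  targets <- library[library$integrate == 1, , drop = FALSE]
  fmeta <- fm$feature_meta
  vip <- vapply(seq_len(nrow(targets)), function(j) {
    lo <- targets$shift[j] - half_window
    hi <- targets$shift[j] + half_window
    hit <- fmeta$right > lo & fmeta$left < hi
    if (!any(hit)) return(NA_real_)
    max(model$vip[hit])
  }, numeric(1))
  stats::setNames(vip, targets$metabolite)
}

#' Two-sample t-tests with Benjamini-Hochberg correction
#'
#' Student (equal-variance) t-test per metabolite between two groups, with
#' BH adjustment across the metabolite set.  Metabolites with zero
#' within-group variance in both groups get NA p-values and a warning.
#'
#' @param integrals a \code{feature_matrix} of metabolite integrals (or any
#'   samples x features matrix with matching \code{sample_meta}).
#' @param groups the two group labels to compare, \code{c(reference, case)}.
#' @return data.frame with \code{metabolite}, \code{p_raw},
#'   \code{p_adjusted}.
#' @export
univariate_tests <- function(integrals, groups) {
  stopifnot(inherits(integrals, "feature_matrix"), length(groups) == 2)
  g <- integrals$sample_meta$group
  a <- integrals$values[g == groups[1], , drop = FALSE]
  b <- integrals$values[g == groups[2], , drop = FALSE]
  if (nrow(a) < 3 || nrow(b) < 3) {
    stop("each group needs >= 3 samples", call. = FALSE)
  }
  p <- vapply(seq_len(ncol(a)), function(j) {
    if (stats::sd(a[, j]) == 0 && stats::sd(b[, j]) == 0) return(NA_real_)
    stats::t.test(a[, j], b[, j], var.equal = TRUE)$p.value
  }, numeric(1))
  if (anyNA(p)) {
    warning(sum(is.na(p)), " metabolite(s) with zero variance in both ",
            "groups; p undefined", call. = FALSE)
  }
  data.frame(
    metabolite = colnames(integrals$values),
    p_raw = p,
    p_adjusted = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE)
}

#' Fold change of group means
#'
#' \code{fc = mean(case) / mean(reference)} per metabolite, so values above
#' 1 mean raised in the case group.
#'
#' @inheritParams univariate_tests
#' @param groups \code{c(reference, case)}.
#' @return data.frame with \code{metabolite}, \code{fc}.
#' @export
fold_change <- function(integrals, groups) {
  stopifnot(inherits(integrals, "feature_matrix"), length(groups) == 2)
  g <- integrals$sample_meta$group
  ref <- colMeans(integrals$values[g == groups[1], , drop = FALSE])
  cas <- colMeans(integrals$values[g == groups[2], , drop = FALSE])
  if (any(ref <= 0) || any(cas <= 0)) {
    stop("non-positive group mean; inspect raw-scale integrals or apply ",
         "an offset before fold-change estimation", call. = FALSE)
  }
  data.frame(metabolite = names(ref), fc = as.vector(cas / ref),
             stringsAsFactors = FALSE)
}

#' Assemble a biomarker table from pipeline results
#'
#' Joins per-metabolite univariate statistics, VIP scores and fold changes
#' into the same record layout as the transcribed printed tables, so
#' selection and the reversal rule apply uniformly to fixture and pipeline
#' output.
#'
#' @param stats data.frame from \code{\link{univariate_tests}}.
#' @param fc data.frame from \code{\link{fold_change}}.
#' @param vip named VIP vector (names = metabolites).
#' @param contrast contrast label.
#' @return a \code{biomarker_table}.
#' @export
biomarker_table <- function(stats, fc, vip, contrast) {
  records <- merge(stats, fc, by = "metabolite", sort = FALSE)
  records$vip <- vip[records$metabolite]
  structure(list(contrast = contrast, records = records, selection = NULL),
            class = "biomarker_table")
}

#' Select biomarkers by significance and VIP
#'
#' Records with raw \code{p < p_threshold} and \code{VIP > vip_threshold},
#' order preserved.  Raw p is used for selection to match the printed
#' tables; BH-adjusted p is carried alongside when available.
#'
#' @param table a \code{biomarker_table}.
#' @param p_threshold raw-p cutoff (default 0.05).
#' @param vip_threshold VIP cutoff (default 1).
#' @return the table with \code{selection} thresholds recorded and
#'   \code{selected} records attached.
#' @export
select_biomarkers <- function(table, p_threshold = 0.05,
                              vip_threshold = 1.0) {
  stopifnot(inherits(table, "biomarker_table"))
  if (is.null(table$records$vip) || anyNA(table$records$vip)) {
    stop("records are missing VIP scores", call. = FALSE)
  }
  keep <- !is.na(table$records$p_raw) &
    table$records$p_raw < p_threshold & table$records$vip > vip_threshold
  table$selection <- c(p = p_threshold, vip = vip_threshold)
  table$selected <- table$records[keep, , drop = FALSE]
  table
}

#' Shared biomarkers with treatment-driven reversal
#'
#' Metabolites selected in both the disease and the treatment contrast
#' whose fold changes cross 1 in opposite directions,
#' \code{(fc_disease - 1) * (fc_treatment - 1) < 0} — i.e. the treatment
#' pushes the disturbed level back toward (and past) the reference.  The
#' plain intersection is returned alongside for transparency.  Names are
#' matched case-insensitively through the alias map.
#'
#' @param table_disease,table_treatment selected \code{biomarker_table}s
#'   (run \code{\link{select_biomarkers}} first, identical thresholds).
#' @return list of class \code{shared_biomarker_set}: \code{metabolites}
#'   (reversal set, display names from the disease table),
#'   \code{intersection}, \code{rule}.
#' @export
shared_reversed <- function(table_disease, table_treatment) {
  for (t in list(table_disease, table_treatment)) {
    if (is.null(t$selected)) {
      stop("run select_biomarkers() on both tables first", call. = FALSE)
    }
  }
  if (!identical(table_disease$selection, table_treatment$selection)) {
    stop("both tables must be selected with identical thresholds",
         call. = FALSE)
  }
  d <- table_disease$selected
  t2 <- table_treatment$selected
  d_key <- normalize_metabolite(d$metabolite)
  t_key <- normalize_metabolite(t2$metabolite)
  if (anyDuplicated(d_key) || anyDuplicated(t_key)) {
    stop("metabolite names do not resolve uniquely: ",
         paste(c(d$metabolite[duplicated(d_key)],
                 t2$metabolite[duplicated(t_key)]), collapse = ", "),
         call. = FALSE)
  }
  common <- intersect(d_key, t_key)
  fc_d <- d$fc[match(common, d_key)]
  fc_t <- t2$fc[match(common, t_key)]
  reversed <- (fc_d - 1) * (fc_t - 1) < 0
  structure(list(
    metabolites = d$metabolite[match(common[reversed], d_key)],
    intersection = d$metabolite[match(common, d_key)],
    rule = paste("selected in both contrasts and fold-change direction",
                 "reversed by treatment: (fc_disease - 1) *",
                 "(fc_treatment - 1) < 0")),
    class = "shared_biomarker_set")
}
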