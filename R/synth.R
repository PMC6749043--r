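# Synthetic 1H-NMR serum cohort generator.
#
# The forward model renders each metabolite as a sum of Lorentzian multiplet
# lines at its tabulated chemical shifts, scales groups by injected fold
# changes, and adds per-sample dilution variation, a slow sinusoidal
# baseline and i.i.d. Gaussian noise.  Peak areas are proportional to
# concentration, as in a quantitative 1D spectrum.

# spectrometer frequency (MHz) used to convert the fixed 7 Hz scalar
# coupling into ppm for multiplet line positions
SPECTROMETER_MHZ <- 599.808
J_COUPLING_HZ <- 7

MULTIPLICITY_CODES <- c("s", "d", "t", "q", "m", "dd", "br")

#' Multiplet line pattern for a multiplicity code
#'
#' Returns the line offsets (ppm, relative to the resonance centre),
#' relative weights (summing to 1) and half-width-at-half-maximum for one
#' resonance.  Conventions: s = 1 line; d = 2 equal lines split by J;
#' t = 3 lines 1:2:1; q = 4 lines 1:3:3:1; dd = 4 equal lines (couplings J
#' and 0.4 J); m and br = a single Lorentzian broadened to 3x the base
#' linewidth.  J is fixed at 7 Hz, converted to ppm at 599.808 MHz.
#'
#' @param multiplicity one of \code{"s","d","t","q","m","dd","br"}.
#' @param linewidth base Lorentzian half-width at half-maximum (ppm).
#' @return data.frame with columns \code{offset}, \code{weight},
#'   \code{width}.
#' @export
multiplet_lines <- function(multiplicity, linewidth) {
  j <- J_COUPLING_HZ / SPECTROMETER_MHZ
  switch(multiplicity,
    s  = data.frame(offset = 0, weight = 1, width = linewidth),
    d  = data.frame(offset = c(-0.5, 0.5) * j, weight = c(0.5, 0.5),
                    width = linewidth),
    t  = data.frame(offset = c(-1, 0, 1) * j, weight = c(1, 2, 1) / 4,
                    width = linewidth),
    q  = data.frame(offset = c(-1.5, -0.5, 0.5, 1.5) * j,
                    weight = c(1, 3, 3, 1) / 8, width = linewidth),
    dd = data.frame(offset = c(-0.7, -0.3, 0.3, 0.7) * j,
                    weight = rep(0.25, 4), width = linewidth),
    m  = data.frame(offset = 0, weight = 1, width = 3 * linewidth),
    br = data.frame(offset = 0, weight = 1, width = 3 * linewidth),
    stop("unknown multiplicity code: ", multiplicity, call. = FALSE)
  )
}

#' Load the metabolite resonance library
#'
#' Reads the delimited fixture describing each metabolite's resonances
#' (chemical shift, multiplicity, relative area), baseline serum level and
#' which shift is used for integration.  Relative areas are validated to sum
#' to 1 per metabolite (within 1e-3) and renormalized exactly.
#'
#' @param path CSV with columns \code{metabolite}, \code{shift},
#'   \code{multiplicity}, \code{relative_area}, \code{base_level},
#'   \code{integrate}. Defaults to the packaged serum library.
#' @return data.frame of class \code{resonance_library}, one row per
#'   resonance.
#' @export
load_resonance_library <- function(path = nmrmetab_extdata("resonance_library.csv")) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("metabolite", "shift", "multiplicity", "relative_area",
                "base_level", "integrate")
  missing <- setdiff(required, names(lib))
  if (length(missing)) {
    stop("resonance library missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(lib) == 0L) stop("resonance library is empty", call. = FALSE)
  if (!is.numeric(lib$shift) || anyNA(lib$shift)) {
    stop("non-numeric chemical shift in resonance library", call. = FALSE)
  }
  bad_mult <- which(!lib$multiplicity %in% MULTIPLICITY_CODES)
  if (length(bad_mult)) {
    stop("unknown multiplicity code '", lib$multiplicity[bad_mult[1]],
         "' in resonance library row ", bad_mult[1],
         " (", lib$metabolite[bad_mult[1]], ")", call. = FALSE)
  }
  if (any(lib$shift < 0 | lib$shift > 10)) {
    stop("chemical shifts must lie in [0, 10] ppm", call. = FALSE)
  }
  if (any(lib$base_level <= 0)) {
    stop("base_level must be > 0 for every metabolite", call. = FALSE)
  }
  for (m in unique(lib$metabolite)) {
    idx <- lib$metabolite == m
    s <- sum(lib$relative_area[idx])
    if (abs(s - 1) > 1e-3) {
      stop("relative areas for '", m, "' sum to ", signif(s, 6),
           ", expected 1", call. = FALSE)
    }
    lib$relative_area[idx] <- lib$relative_area[idx] / s
    if (sum(lib$integrate[idx]) != 1L) {
      # default: integrate at the first listed shift
      lib$integrate[idx] <- 0L
      lib$integrate[which(idx)[1]] <- 1L
    }
  }
  class(lib) <- c("resonance_library", "data.frame")
  lib
}

#' Cohort design for synthetic spectra
#'
#' Collects the simulation conditions: group structure, per-sample dilution
#' spread, noise, baseline, lineshape and the ppm grid.  Defaults emulate a
#' four-group rat cohort of 10 animals per group.
#'
#' @param groups ordered group labels; the first is the reference unless
#'   \code{reference_group} says otherwise.
#' @param n_per_group samples per group (>= 3).
#' @param dilution_sd log-scale SD of the per-sample global dilution factor.
#' @param noise_sd additive Gaussian noise SD per spectral point
#'   (intensity units; a unit-concentration singlet peaks near
#'   \code{1/(pi * linewidth)}).
#' @param baseline_amplitude scale of the slow sinusoidal baseline.
#' @param linewidth Lorentzian half-width at half-maximum (ppm).
#' @param ppm_grid c(min ppm, max ppm, number of points), points >= 1000.
#' @param bio_cv per-sample biological coefficient of variation of
#'   metabolite levels (log-normal around the group mean).
#' @param baseline_cv per-sample coefficient of variation of the baseline
#'   amplitude around the cohort's common envelope.
#' @param reference_group label of the group simulated at base levels.
#' @param seed integer seed making the cohort reproducible.
#' @return list of class \code{cohort_design}.
#' @export
cohort_design <- function(groups = c("WKY-N", "SHR-N", "SHR-L", "SHR-H"),
                          n_per_group = 10,
                          dilution_sd = 0.1,
                          noise_sd = 0.3,
                          baseline_amplitude = 2,
                          linewidth = 0.002,
                          ppm_grid = c(0.5, 9.0, 16384),
                          bio_cv = 0.1,
                          baseline_cv = 0.05,
                          reference_group = groups[1],
                          seed = 1) {
  stopifnot(length(groups) >= 1, !anyDuplicated(groups))
  if (n_per_group < 3) stop("n_per_group must be >= 3", call. = FALSE)
  if (length(ppm_grid) != 3 || ppm_grid[3] < 1000) {
    stop("ppm_grid must be c(min, max, n) with n >= 1000", call. = FALSE)
  }
  if (ppm_grid[1] >= ppm_grid[2]) {
    stop("ppm_grid min must be below max", call. = FALSE)
  }
  if (linewidth <= 0) stop("linewidth must be > 0", call. = FALSE)
  if (!reference_group %in% groups) {
    stop("reference_group must be one of the group labels", call. = FALSE)
  }
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 dilution_sd = dilution_sd, noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 linewidth = linewidth, ppm_grid = ppm_grid,
                 bio_cv = bio_cv, baseline_cv = baseline_cv,
                 reference_group = reference_group,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

ppm_axis <- function(design) {
  ppm <- seq(design$ppm_grid[1], design$ppm_grid[2],
             length.out = design$ppm_grid[3])
  if (any(diff(ppm) <= 0)) {
    stop("ppm grid is not strictly increasing", call. = FALSE)
  }
  ppm
}

# unit-concentration spectrum of every metabolite on the design grid
# (points x metabolites); the expensive part of the forward model, shared
# across samples because the lineshape does not depend on the sample
metabolite_basis <- function(library, design) {
  ppm <- ppm_axis(design)
  mets <- unique(library$metabolite)
  basis <- matrix(0, nrow = length(ppm), ncol = length(mets),
                  dimnames = list(NULL, mets))
  for (i in seq_len(nrow(library))) {
    lines <- multiplet_lines(library$multiplicity[i], design$linewidth)
    for (k in seq_len(nrow(lines))) {
      centre <- library$shift[i] + lines$offset[k]
      w <- lines$width[k]
      area <- library$relative_area[i] * lines$weight[k]
      # unit-area Lorentzian: (1/pi) * w / ((x - x0)^2 + w^2)
      basis[, library$metabolite[i]] <- basis[, library$metabolite[i]] +
        area * (w / pi) / ((ppm - centre)^2 + w^2)
    }
  }
  basis
}

baseline_profile <- function(ppm, amplitude, phase = 0, cycles = 1.5) {
  span <- diff(range(ppm))
  amplitude * (1 + 0.5 * sin(2 * pi * cycles * (ppm - ppm[1]) / span + phase))
}

#' Simulate a single 1H-NMR spectrum
#'
#' Renders \code{intensity = dilution * (sum_m level_m * multiplets_m +
#' baseline) + noise} on the design's ppm grid.  The dilution factor
#' multiplies the whole sample - metabolite signals and the macromolecule
#' baseline alike - as it does physically; only the instrumental noise sits
#' outside it.  Uses the session RNG; seed upstream (or via
#' \code{\link{simulate_cohort}}) for reproducibility.
#'
#' @param library a \code{resonance_library}.
#' @param levels named non-negative concentrations, one per metabolite in
#'   the library.
#' @param design a \code{\link{cohort_design}}.
#' @param sample_id,group metadata attached to the spectrum.
#' @param basis optional precomputed \code{metabolite_basis} (points x
#'   metabolites) to avoid re-rendering lineshapes.
#' @param baseline_phase phase of the slow sinusoidal baseline envelope;
#'   fixed per cohort (the macromolecule background has a common shape
#'   across samples of one study).
#' @param baseline_scale per-sample multiplier on the baseline amplitude.
#' @param dilution per-sample dilution factor; drawn from the design's
#'   log-normal when NULL.
#' @return list of class \code{nmr_spectrum} with fields \code{ppm},
#'   \code{intensity}, \code{sample_id}, \code{group}.
#' @export
simulate_spectrum <- function(library, levels, design, sample_id = "s1",
                              group = design$groups[1], basis = NULL,
                              baseline_phase = 0, baseline_scale = 1,
                              dilution = NULL) {
  if (is.null(basis)) basis <- metabolite_basis(library, design)
  mets <- colnames(basis)
  if (is.null(names(levels)) || !all(mets %in% names(levels))) {
    stop("'levels' must be named and cover every library metabolite",
         call. = FALSE)
  }
  lv <- levels[mets]
  if (any(lv < 0)) stop("metabolite levels must be >= 0", call. = FALSE)
  ppm <- ppm_axis(design)
  if (is.null(dilution)) {
    dilution <- if (design$dilution_sd > 0) {
      stats::rlnorm(1, meanlog = 0, sdlog = design$dilution_sd)
    } else 1
  }
  base <- if (design$baseline_amplitude > 0) {
    baseline_scale * baseline_profile(ppm, design$baseline_amplitude,
                                      phase = baseline_phase)
  } else 0
  noise <- if (design$noise_sd > 0) {
    stats::rnorm(length(ppm), 0, design$noise_sd)
  } else 0
  intensity <- dilution * (as.vector(basis %*% lv) + base) + noise
  if (!all(is.finite(intensity))) {
    stop("simulated intensities are not finite", call. = FALSE)
  }
  structure(list(ppm = ppm, intensity = intensity, sample_id = sample_id,
                 group = group, dilution = dilution),
            class = "nmr_spectrum")
}

#' Build an effect table from a transcribed biomarker table
#'
#' Turns the FC column of a printed biomarker table into per-metabolite
#' group-mean ratios for one contrast, e.g. \code{"SHR-N_vs_WKY-N"} (case
#' over reference).
#'
#' @param table a \code{biomarker_table} (see
#'   \code{\link{load_biomarker_table}}) or data.frame with columns
#'   \code{metabolite} and \code{fc}.
#' @param contrast label of the form \code{"CASE_vs_REFERENCE"}.
#' @return data.frame with columns \code{metabolite}, \code{contrast},
#'   \code{fold_change}, of class \code{effect_table}.
#' @export
effect_table <- function(table, contrast) {
  records <- if (is.list(table) && !is.null(table$records)) table$records else table
  if (any(records$fc <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (anyDuplicated(records$metabolite)) {
    stop("one row per metabolite per contrast required", call. = FALSE)
  }
  structure(data.frame(metabolite = records$metabolite, contrast = contrast,
                       fold_change = records$fc, stringsAsFactors = FALSE),
            class = c("effect_table", "data.frame"))
}

# resolve per-group, per-metabolite mean multipliers from chained contrasts
# "A_vs_B": mean_A = mean_B * FC; the reference group sits at 1
resolve_group_multipliers <- function(effects, design, mets) {
  mult <- matrix(NA_real_, nrow = length(mets), ncol = length(design$groups),
                 dimnames = list(mets, design$groups))
  mult[, design$reference_group] <- 1
  if (!is.null(effects) && nrow(effects)) {
    # printed tables and the library may differ in case; match canonically
    met_key <- normalize_metabolite(mets)
    eff_key <- normalize_metabolite(effects$metabolite)
    unknown <- unique(effects$metabolite[!eff_key %in% met_key])
    if (length(unknown)) {
      stop("effect table references metabolites absent from the library: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    effects$metabolite <- mets[match(eff_key, met_key)]
    parts <- strsplit(unique(effects$contrast), "_vs_", fixed = TRUE)
    for (p in parts) {
      if (length(p) != 2 || !all(p %in% design$groups)) {
        stop("contrast '", paste(p, collapse = "_vs_"),
             "' references a group outside the design", call. = FALSE)
      }
    }
    # chain contrasts until all reachable groups are resolved
    for (pass in seq_along(parts)) {
      for (p in parts) {
        case <- p[1]; ref <- p[2]
        lab <- paste(case, ref, sep = "_vs_")
        if (all(is.na(mult[, case])) && !anyNA(mult[, ref])) {
          fc <- rep(1, length(mets)); names(fc) <- mets
          rows <- effects[effects$contrast == lab, ]
          fc[rows$metabolite] <- rows$fold_change
          mult[, case] <- mult[, ref] * fc
        }
      }
    }
  }
  # groups untouched by any contrast sit at the reference level
  mult[is.na(mult)] <- 1
  mult
}

#' Simulate a multi-group cohort of spectra
#'
#' The reference group's mean metabolite levels are the library's
#' \code{base_level}; each contrasted group's mean is scaled by the effect
#' table's fold changes (contrasts chain, so a treatment contrast against a
#' disease group composes with the disease contrast).  Per-sample levels are
#' log-normal around the group mean with CV \code{design$bio_cv};
#' per-sample dilution factors are log-normal with SD
#' \code{design$dilution_sd}.  Deterministic given \code{design$seed}.
#'
#' @param library a \code{resonance_library}.
#' @param effects an \code{\link{effect_table}} (or NULL for a null cohort).
#' @param design a \code{\link{cohort_design}}.
#' @return list of class \code{nmr_spectrum_set}: \code{ppm}, an
#'   \code{intensities} samples-by-points matrix, \code{sample_meta},
#'   \code{design}, \code{truth} (the effect table), \code{levels} (the
#'   per-sample true concentrations).
#' @export
simulate_cohort <- function(library, effects, design) {
  mets <- unique(library$metabolite)
  base <- vapply(mets, function(m) library$base_level[library$metabolite == m][1],
                 numeric(1))
  mult <- resolve_group_multipliers(effects, design, mets)
  basis <- metabolite_basis(library, design)
  ppm <- ppm_axis(design)
  n <- design$n_per_group * length(design$groups)
  with_seed(design$seed, {
    intensities <- matrix(0, nrow = n, ncol = length(ppm))
    levels_mat <- matrix(0, nrow = n, ncol = length(mets),
                         dimnames = list(NULL, mets))
    sample_id <- character(n); group <- character(n); dilution <- numeric(n)
    s_bio <- sqrt(log(1 + design$bio_cv^2))
    s_base <- sqrt(log(1 + design$baseline_cv^2))
    # one baseline envelope per cohort; samples vary only in its amplitude
    phase <- stats::runif(1, 0, 2 * pi)
    i <- 0L
    for (g in design$groups) {
      gmean <- base * mult[, g]
      for (k in seq_len(design$n_per_group)) {
        i <- i + 1L
        lv <- if (s_bio > 0) {
          gmean * stats::rlnorm(length(mets), meanlog = -s_bio^2 / 2,
                                sdlog = s_bio)
        } else gmean
        names(lv) <- mets
        bscale <- if (s_base > 0) {
          stats::rlnorm(1, meanlog = -s_base^2 / 2, sdlog = s_base)
        } else 1
        sp <- simulate_spectrum(library, lv, design,
                                sample_id = sprintf("%s_%02d", g, k),
                                group = g, basis = basis,
                                baseline_phase = phase,
                                baseline_scale = bscale)
        intensities[i, ] <- sp$intensity
        levels_mat[i, ] <- lv
        sample_id[i] <- sp$sample_id
        group[i] <- g
        dilution[i] <- sp$dilution
      }
    }
    structure(list(
      ppm = ppm, intensities = intensities,
      sample_meta = data.frame(sample_id = sample_id, group = group,
                               dilution = dilution,
                               stringsAsFactors = FALSE),
      design = design, truth = effects, levels = levels_mat),
      class = "nmr_spectrum_set")
  })
}

#' Extract individual spectra from a spectrum set
#'
#' @param set an \code{nmr_spectrum_set}.
#' @return list of \code{nmr_spectrum} objects sharing one ppm grid.
#' @export
as_spectra <- function(set) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  lapply(seq_len(nrow(set$intensities)), function(i) {
    structure(list(ppm = set$ppm, intensity = set$intensities[i, ],
                   sample_id = set$sample_meta$sample_id[i],
                   group = set$sample_meta$group[i]),
              class = "nmr_spectrum")
  })
}

#' Write / read a spectrum set as plain text
#'
#' The wide CSV has one row per sample and one column per ppm grid point;
#' values are printed with 17 significant digits so the round trip is
#' lossless at double precision.  Sample metadata travels in a sidecar CSV.
#'
#' @param set an \code{nmr_spectrum_set}.
#' @param data_path path for the wide intensity CSV.
#' @param meta_path path for the sample-metadata CSV.
#' @return \code{data_path}, invisibly.
#' @export
write_spectrum_set <- function(set, data_path, meta_path) {
  stopifnot(inherits(set, "nmr_spectrum_set"))
  fmt <- function(x) sprintf("%.17g", x)
  header <- paste(c("sample_id", fmt(set$ppm)), collapse = ",")
  rows <- vapply(seq_len(nrow(set$intensities)), function(i) {
    paste(c(set$sample_meta$sample_id[i], fmt(set$intensities[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), data_path)
  utils::write.csv(set$sample_meta, meta_path, row.names = FALSE)
  invisible(data_path)
}

#' @rdname write_spectrum_set
#' @export
read_spectrum_set <- function(data_path, meta_path) {
  lines <- readLines(data_path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  ppm <- as.numeric(header[-1])
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  intensities <- t(vapply(body, function(x) as.numeric(x[-1]),
                          numeric(length(ppm))))
  sample_meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  structure(list(ppm = ppm, intensities = intensities,
                 sample_meta = sample_meta, design = NULL, truth = NULL),
            class = "nmr_spectrum_set")
}
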