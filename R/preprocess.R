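# Spectral preprocessing: water-region exclusion, adaptive binning,
# probabilistic quotient normalization (PQN) and pareto scaling.
#
# The stages mirror standard serum 1H-NMR practice: exclude the residual
# water band (4.33-5.50 ppm), integrate adaptively placed bins averaging
# 0.015 ppm, correct per-sample dilution by PQN, then mean-centre and
# pareto-scale before multivariate modelling.

DEFAULT_EXCLUSION <- c(4.33, 5.50)

#' Exclude a chemical-shift region from a spectrum
#'
#' Drops every grid point with ppm in \code{[low, high]} (the residual water
#' band by default); all other points are preserved in order.
#'
#' @param x an \code{nmr_spectrum} or \code{nmr_spectrum_set}.
#' @param low,high interval bounds in ppm, \code{low < high}.
#' @return object of the same class without the excluded points.
#' @export
exclude_region <- function(x, low = DEFAULT_EXCLUSION[1],
                           high = DEFAULT_EXCLUSION[2]) {
  if (low >= high) stop("exclusion requires low < high", call. = FALSE)
  UseMethod("exclude_region")
}

#' @export
exclude_region.nmr_spectrum <- function(x, low = DEFAULT_EXCLUSION[1],
                                        high = DEFAULT_EXCLUSION[2]) {
  keep <- x$ppm < low | x$ppm > high
  if (!any(keep)) stop("exclusion would remove the entire spectrum",
                       call. = FALSE)
  x$ppm <- x$ppm[keep]
  x$intensity <- x$intensity[keep]
  x
}

#' @export
exclude_region.nmr_spectrum_set <- function(x, low = DEFAULT_EXCLUSION[1],
                                            high = DEFAULT_EXCLUSION[2]) {
  keep <- x$ppm < low | x$ppm > high
  if (!any(keep)) stop("exclusion would remove the entire spectrum",
                       call. = FALSE)
  x$ppm <- x$ppm[keep]
  x$intensities <- x$intensities[, keep, drop = FALSE]
  x$excluded <- rbind(x$excluded, c(low, high))
  x
}

# contiguous runs of the (possibly gapped) retained grid, as index ranges
grid_segments <- function(ppm) {
  step <- stats::median(diff(ppm))
  breaks <- which(diff(ppm) > 3 * step)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(ppm))
  data.frame(from = starts, to = ends)
}

#' Adaptive binning of a cohort of spectra
#'
#' Seeds uniform bin boundaries at \code{target_width} spacing within each
#' contiguous retained segment, then moves every interior boundary to the
#' lowest point of the cohort-mean spectrum within +/- 40 percent of the
#' target width (ties resolved toward the seed), and merges bins narrower
#' than 25 percent of the target into their narrower neighbour.  Boundary
#' placement at local minima avoids splitting peaks across bins.  Each cell
#' of the result is the trapezoidal integral of that sample's intensity
#' over the bin, so a row's bin integrals sum to its total retained
#' integral.
#'
#' @param set an \code{nmr_spectrum_set} (post-exclusion) or a list of
#'   \code{nmr_spectrum} sharing one grid.
#' @param target_width target mean bin width in ppm (0.015 by default).
#' @return a \code{feature_matrix} with stage \code{"binned"}.
#' @export
adaptive_bin <- function(set, target_width = 0.015) {
  if (target_width <= 0) stop("target_width must be > 0", call. = FALSE)
  if (is.list(set) && !inherits(set, "nmr_spectrum_set")) {
    set <- bind_spectra(set)
  }
  if (nrow(set$intensities) < 2) {
    stop("adaptive binning needs at least 2 spectra", call. = FALSE)
  }
  ppm <- set$ppm
  meanspec <- colMeans(set$intensities)
  segs <- grid_segments(ppm)
  edges_left <- numeric(0); edges_right <- numeric(0)
  idx_bounds <- list()
  for (s in seq_len(nrow(segs))) {
    lo <- segs$from[s]; hi <- segs$to[s]
    seg_ppm <- ppm[lo:hi]
    seg_len <- seg_ppm[length(seg_ppm)] - seg_ppm[1]
    n_bins <- max(1L, round(seg_len / target_width))
    seed_pos <- seg_ppm[1] + seg_len * seq_len(n_bins - 1) / n_bins
    bound_idx <- integer(0)
    if (n_bins > 1) {
      window <- 0.4 * target_width
      bound_idx <- vapply(seed_pos, function(b) {
        cand <- which(seg_ppm >= b - window & seg_ppm <= b + window)
        vals <- meanspec[lo:hi][cand]
        tol <- 1e-9 * (max(abs(vals)) + 1e-300)
        near_min <- cand[vals <= min(vals) + tol]
        # ties (e.g. flat spectra) fall back to the seed position
        near_min[which.min(abs(seg_ppm[near_min] - b))]
      }, integer(1))
      bound_idx <- sort(unique(bound_idx))
    }
    all_bounds <- c(1L, bound_idx, hi - lo + 1L)
    # merge undersized bins with the narrower adjacent bin
    repeat {
      widths <- diff(seg_ppm[all_bounds])
      narrow <- which(widths < 0.25 * target_width)
      if (!length(narrow) || length(widths) == 1L) break
      k <- narrow[1]
      left_w <- if (k > 1) widths[k - 1] else Inf
      right_w <- if (k < length(widths)) widths[k + 1] else Inf
      drop <- if (left_w <= right_w) k else k + 1L  # interior boundary index
      all_bounds <- all_bounds[-drop]
    }
    nb <- length(all_bounds) - 1L
    for (k in seq_len(nb)) {
      idx_bounds[[length(idx_bounds) + 1L]] <-
        c(lo + all_bounds[k] - 1L, lo + all_bounds[k + 1L] - 1L)
      edges_left <- c(edges_left, seg_ppm[all_bounds[k]])
      edges_right <- c(edges_right, seg_ppm[all_bounds[k + 1L]])
    }
  }
  values <- matrix(0, nrow = nrow(set$intensities), ncol = length(idx_bounds))
  dx <- diff(ppm)
  for (j in seq_along(idx_bounds)) {
    a <- idx_bounds[[j]][1]; b <- idx_bounds[[j]][2]
    w <- dx[a:(b - 1)]
    left <- set$intensities[, a:(b - 1), drop = FALSE]
    right <- set$intensities[, (a + 1):b, drop = FALSE]
    values[, j] <- as.vector((left + right) %*% w) / 2
  }
  feature_matrix(values,
                 feature_meta = data.frame(left = edges_left,
                                           right = edges_right,
                                           center = (edges_left + edges_right) / 2),
                 sample_meta = set$sample_meta[, c("sample_id", "group")],
                 stage = "binned")
}

# assemble a set from a list of spectra on one common grid
bind_spectra <- function(spectra) {
  ppm <- spectra[[1]]$ppm
  for (sp in spectra[-1]) {
    if (length(sp$ppm) != length(ppm) || any(sp$ppm != ppm)) {
      stop("spectra must share a common ppm grid", call. = FALSE)
    }
  }
  structure(list(
    ppm = ppm,
    intensities = do.call(rbind, lapply(spectra, `[[`, "intensity")),
    sample_meta = data.frame(
      sample_id = vapply(spectra, `[[`, character(1), "sample_id"),
      group = vapply(spectra, `[[`, character(1), "group"),
      stringsAsFactors = FALSE)),
    class = "nmr_spectrum_set")
}

#' Sample-by-feature intensity matrix
#'
#' Container shared by the binned, normalized and scaled stages: a numeric
#' samples x features matrix plus per-feature bin edges and per-sample
#' metadata.
#'
#' @param values numeric matrix, samples in rows.
#' @param feature_meta data.frame with \code{left}, \code{right},
#'   \code{center} (ppm) per feature.
#' @param sample_meta data.frame with \code{sample_id}, \code{group}.
#' @param stage one of \code{"binned"}, \code{"normalized"},
#'   \code{"scaled"}, or \code{"integrals"} for metabolite-level tables.
#' @return object of class \code{feature_matrix}.
#' @export
feature_matrix <- function(values, feature_meta, sample_meta,
                           stage = c("binned", "normalized", "scaled",
                                     "integrals")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (nrow(values) != nrow(sample_meta)) {
    stop("row count must equal number of samples", call. = FALSE)
  }
  if (ncol(values) != nrow(feature_meta)) {
    stop("feature metadata must describe every column", call. = FALSE)
  }
  # bin-partition invariant applies to spectral bins; metabolite
  # integration windows are allowed to overlap (they are flagged instead)
  if (stage != "integrals" && !is.null(feature_meta$left)) {
    ord <- order(feature_meta$left)
    if (any(diff(feature_meta$left[ord]) < 0) ||
        any(feature_meta$right[ord][-nrow(feature_meta)] >
            feature_meta$left[ord][-1] + 1e-9)) {
      stop("bin edges must be sorted and non-overlapping", call. = FALSE)
    }
  }
  structure(list(values = values, feature_meta = feature_meta,
                 sample_meta = sample_meta, stage = stage),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d samples x %d features, stage '%s'>\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Probabilistic quotient normalization
#'
#' Corrects unequal per-sample dilution: each row is first scaled to the
#' cohort's median total integral, then divided by the median of its
#' feature-wise quotients against the reference spectrum (the median
#' spectrum over the reference policy's rows).  Quotients are computed only
#' over features whose reference value exceeds a small positive floor
#' (1 percent of the reference's median positive value), so noise-only
#' features do not destabilize the median.
#'
#' @param fm a binned \code{feature_matrix}.
#' @param reference \code{"all"} (median spectrum over all samples, the
#'   default) or a group label restricting the reference rows.
#' @return list with \code{matrix} (stage \code{"normalized"}) and
#'   \code{report}: per-sample total-integral factor, PQN quotient and their
#'   product, the overall dilution-factor estimate.
#' @export
pqn_normalize <- function(fm, reference = "all") {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$stage != "binned") {
    stop("pqn_normalize expects a binned feature matrix", call. = FALSE)
  }
  X <- fm$values
  totals <- rowSums(X)
  zero <- which(totals <= 0 | apply(X, 1, function(r) all(r == 0)))
  if (length(zero)) {
    stop("sample(s) with non-positive total integral: ",
         paste(fm$sample_meta$sample_id[zero], collapse = ", "),
         call. = FALSE)
  }
  target <- stats::median(totals)
  Xn <- X * (target / totals)
  ref_rows <- if (identical(reference, "all")) {
    seq_len(nrow(Xn))
  } else {
    rows <- which(fm$sample_meta$group == reference)
    if (!length(rows)) stop("no samples in reference group '", reference,
                            "'", call. = FALSE)
    rows
  }
  ref <- apply(Xn[ref_rows, , drop = FALSE], 2, stats::median)
  pos <- ref[ref > 0]
  if (!length(pos)) stop("reference spectrum has no positive features",
                         call. = FALSE)
  floor_val <- 0.01 * stats::median(pos)
  eligible <- which(ref > floor_val)
  quotients <- apply(Xn[, eligible, drop = FALSE], 1, function(r) {
    stats::median(r / ref[eligible])
  })
  out <- Xn / quotients
  report <- data.frame(
    sample_id = fm$sample_meta$sample_id,
    total_factor = totals / target,
    pqn_quotient = quotients,
    dilution = (totals / target) * quotients,
    stringsAsFactors = FALSE)
  attr(report, "reference") <- if (identical(reference, "all")) {
    "median spectrum over all samples"
  } else {
    paste0("median spectrum over group '", reference, "'")
  }
  fm$values <- out
  fm$stage <- "normalized"
  list(matrix = fm, report = report)
}

#' Mean-centre and pareto-scale features
#'
#' Each column is centred to mean zero and divided by the square root of
#' its standard deviation, so the post-scaling variance of a column equals
#' its pre-scaling standard deviation; this damps dominance of
#' high-variance features while keeping weak signals visible.  Constant
#' columns are set to zero (with a warning) rather than dropped, keeping
#' feature indices stable.
#'
#' @param fm a normalized \code{feature_matrix} (or metabolite integrals).
#' @return a \code{feature_matrix} with stage \code{"scaled"}; constant
#'   columns are recorded in attribute \code{"constant_features"}.
#' @export
scale_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!fm$stage %in% c("normalized", "integrals")) {
    stop("scale_features expects a normalized feature matrix", call. = FALSE)
  }
  if (nrow(fm$values) < 2) {
    stop("scaling needs at least 2 samples", call. = FALSE)
  }
  X <- fm$values
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  Xc <- sweep(X, 2, mu)
  const <- which(sds == 0)
  sds_safe <- ifelse(sds > 0, sds, 1)
  Xs <- sweep(Xc, 2, sqrt(sds_safe), "/")
  if (length(const)) {
    Xs[, const] <- 0
    warning(length(const), " constant feature(s) set to zero after scaling",
            call. = FALSE)
  }
  fm$values <- Xs
  fm$stage <- "scaled"
  attr(fm, "constant_features") <- const
  attr(fm, "center") <- mu
  attr(fm, "pareto_sd") <- sds
  fm
}

#' Write a feature matrix to CSV
#'
#' Values go to \code{path}; bin edges, sample metadata and the stage go to
#' a sidecar \code{<path>.meta.csv} so the matrix is self-describing.
#'
#' @param fm a \code{feature_matrix}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$values)
  names(df) <- sprintf("bin_%0.4f", fm$feature_meta$center)
  out <- cbind(fm$sample_meta, df)
  utils::write.csv(out, path, row.names = FALSE)
  meta <- cbind(stage = fm$stage, fm$feature_meta)
  utils::write.csv(meta, paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}
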