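# Multivariate modelling: PCA, two-class OPLS-DA via NIPALS orthogonal
# signal correction, repeated twofold cross-validated Q2, permutation
# validation, VIP scores and correlation-coloured coefficient loadings.
#
# OPLS-DA follows the orthogonal-projections scheme: components of X
# uncorrelated with the class response are extracted and removed first,
# then a single predictive PLS component is fitted on the filtered X.
# Class membership is coded -1/+1 (the second factor level positive), and
# the predictive weight vector is signed so the second-listed class has a
# positive mean score.

as_matrix_input <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

#' Principal component analysis of a scaled feature matrix
#'
#' Thin wrapper over the singular value decomposition (via
#' \code{\link[stats]{prcomp}}) returning scores, orthonormal loadings and
#' the fraction of variance explained per component.
#'
#' @param x a scaled \code{feature_matrix} or numeric matrix.
#' @param n_components number of components (at most
#'   \code{min(samples - 1, features)}).
#' @return list of class \code{pca_model}: \code{scores},
#'   \code{loadings}, \code{explained_variance_fraction}.
#' @export
fit_pca <- function(x, n_components = 2) {
  X <- as_matrix_input(x)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components > kmax) {
    stop("n_components must be <= min(samples - 1, features) = ", kmax,
         call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x[, seq_len(n_components), drop = FALSE],
    loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
    explained_variance_fraction = expl[seq_len(n_components)]),
    class = "pca_model")
}

# two-class response coded -1/+1; second level positive
code_classes <- function(classes) {
  f <- if (is.factor(classes)) droplevels(classes) else factor(classes)
  lev <- levels(f)
  if (length(lev) != 2) {
    stop("exactly 2 classes are required; fit contrasts pairwise",
         call. = FALSE)
  }
  counts <- table(f)
  if (any(counts < 3)) {
    stop("each class needs >= 3 samples", call. = FALSE)
  }
  list(y = ifelse(f == lev[2], 1, -1), levels = lev)
}

# core OPLS decomposition on (X, y); returns weights/scores/loadings of the
# orthogonal components and the single predictive component
opls_core <- function(X, y, n_orthogonal) {
  yc <- y - mean(y)
  W_o <- matrix(0, ncol(X), 0); P_o <- matrix(0, ncol(X), 0)
  T_o <- matrix(0, nrow(X), 0)
  Xf <- X
  w <- as.vector(crossprod(Xf, yc))
  w <- w / sqrt(sum(w^2))
  if (n_orthogonal > 0) {
    for (a in seq_len(n_orthogonal)) {
      t_p <- as.vector(Xf %*% w)
      p <- as.vector(crossprod(Xf, t_p)) / sum(t_p^2)
      w_o <- p - sum(w * p) * w
      nrm <- sqrt(sum(w_o^2))
      if (nrm < 1e-12) break  # no orthogonal variation left
      w_o <- w_o / nrm
      t_o <- as.vector(Xf %*% w_o)
      p_o <- as.vector(crossprod(Xf, t_o)) / sum(t_o^2)
      Xf <- Xf - tcrossprod(t_o, p_o)
      W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
      T_o <- cbind(T_o, t_o)
      w <- as.vector(crossprod(Xf, yc))
      w <- w / sqrt(sum(w^2))
    }
  }
  t_p <- as.vector(Xf %*% w)
  p <- as.vector(crossprod(Xf, t_p)) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)
  # sign convention: positive class (second level) gets positive mean score
  if (mean(t_p[y > 0]) < mean(t_p[y < 0])) {
    w <- -w; t_p <- -t_p; p <- -p; q <- -q
  }
  list(w = w, t = t_p, p = p, q = q, W_o = W_o, P_o = P_o, T_o = T_o,
       y_mean = mean(y))
}

# remove the fitted orthogonal variation from new data
filter_orthogonal <- function(core, Xnew) {
  if (ncol(core$W_o) == 0) return(Xnew)
  for (a in seq_len(ncol(core$W_o))) {
    t_o <- Xnew %*% core$W_o[, a]
    Xnew <- Xnew - tcrossprod(t_o, core$P_o[, a])
  }
  Xnew
}

predict_opls <- function(core, Xnew) {
  Xf <- filter_orthogonal(core, Xnew)
  as.vector(Xf %*% core$w) * core$q + core$y_mean
}

#' Fit a two-class OPLS-DA model
#'
#' Extracts \code{n_orthogonal} components of X uncorrelated with class
#' membership, then one predictive PLS component on the filtered X.  With
#' \code{n_orthogonal = 0} the predictive component coincides with a
#' one-component PLS1 fit.
#'
#' @param x a scaled \code{feature_matrix} or numeric matrix.
#' @param classes two-class labels (factor or character); the second factor
#'   level is coded +1 and gets positive predictive scores.
#' @param n_orthogonal number of class-orthogonal components (>= 0).
#' @return list of class \code{oplsda_model} with predictive and orthogonal
#'   scores/weights/loadings, \code{r2x} (split into predictive and
#'   orthogonal parts), \code{r2y}, the VIP vector and the class coding.
#' @export
fit_oplsda <- function(x, classes, n_orthogonal = 1) {
  X <- as_matrix_input(x)
  cc <- code_classes(classes)
  if (length(cc$y) != nrow(X)) stop("classes must match rows", call. = FALSE)
  core <- opls_core(X, cc$y, n_orthogonal)
  yc <- cc$y - mean(cc$y)
  ssx <- sum(X^2)
  ssx_pred <- sum(core$t^2) * sum(core$p^2)
  ssx_orth <- if (ncol(core$T_o)) {
    sum(vapply(seq_len(ncol(core$T_o)), function(a) {
      sum(core$T_o[, a]^2) * sum(core$P_o[, a]^2)
    }, numeric(1)))
  } else 0
  resid_y <- yc - core$t * core$q
  model <- structure(list(
    predictive_scores = core$t,
    predictive_weights = core$w,
    predictive_loadings = core$p,
    q_loading = core$q,
    orthogonal_scores = core$T_o,
    orthogonal_weights = core$W_o,
    orthogonal_loadings = core$P_o,
    r2x = (ssx_pred + ssx_orth) / ssx,
    r2x_predictive = ssx_pred / ssx,
    r2x_orthogonal = ssx_orth / ssx,
    r2y = 1 - sum(resid_y^2) / sum(yc^2),
    q2 = NA_real_,
    classes = cc$levels,
    y = cc$y,
    n_orthogonal = ncol(core$T_o),
    core = core),
    class = "oplsda_model")
  model$vip <- compute_vip(model)
  model
}

#' Variable importance in the projection
#'
#' For the default single predictive component,
#' \code{VIP_j = sqrt(p_features) * |w_j|} with the weight vector of unit
#' norm, so the mean squared VIP equals 1 exactly.  \code{type = "total"}
#' additionally weighs the orthogonal components by the X variance they
#' explain — useful for diagnosing what dominates X, but the discriminant
#' reading (and the VIP > 1 selection convention) uses the predictive
#' component only.
#'
#' @param model a fitted \code{oplsda_model}.
#' @param type \code{"predictive"} (default) or \code{"total"}.
#' @return numeric VIP vector, one value per feature.
#' @export
compute_vip <- function(model, type = c("predictive", "total")) {
  type <- match.arg(type)
  if (!inherits(model, "oplsda_model") || is.null(model$predictive_weights)) {
    stop("compute_vip needs a fitted oplsda_model", call. = FALSE)
  }
  p_feat <- length(model$predictive_weights)
  if (type == "predictive") {
    return(sqrt(p_feat) * abs(model$predictive_weights))
  }
  # total-model variant: weights squared, averaged with SSX-explained
  ss <- c(model$r2x_predictive,
          if (ncol(model$orthogonal_weights)) {
            vapply(seq_len(ncol(model$orthogonal_weights)), function(a) {
              sum(model$orthogonal_scores[, a]^2) *
                sum(model$orthogonal_loadings[, a]^2)
            }, numeric(1))
          })
  W <- cbind(model$predictive_weights, model$orthogonal_weights)
  sqrt(p_feat * as.vector(W^2 %*% ss) / sum(ss))
}

#' Repeated twofold cross-validated Q2
#'
#' Stratified random halves; within each training fold the orthogonal
#' components and the predictive component are re-estimated from scratch
#' (no information from the held-out half), the held-out coded responses
#' are predicted, and \code{Q2 = 1 - PRESS/TSS} is pooled over both folds
#' and averaged over repeats.  Deterministic given \code{seed}.
#'
#' @inheritParams fit_oplsda
#' @param n_repeats number of random twofold splits to average (>= 1).
#' @param seed integer seed.
#' @return Q2 (a scalar; may be negative for uninformative data).
#' @export
cross_validate_q2 <- function(x, classes, n_orthogonal = 1, n_repeats = 7,
                              seed = 1) {
  X <- as_matrix_input(x)
  cc <- code_classes(classes)
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  y <- cc$y
  with_seed(seed, {
    q2s <- vapply(seq_len(n_repeats), function(r) {
      fold <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        half <- floor(length(idx) / 2)
        fold[idx[seq_len(half)]] <- 1L
        fold[idx[-seq_len(half)]] <- 2L
      }
      press <- 0; tss <- 0
      for (f in 1:2) {
        test <- fold == f
        core <- opls_core(X[!test, , drop = FALSE], y[!test], n_orthogonal)
        y_hat <- predict_opls(core, X[test, , drop = FALSE])
        press <- press + sum((y[test] - y_hat)^2)
        tss <- tss + sum((y[test] - mean(y[!test]))^2)
      }
      1 - press / tss
    }, numeric(1))
    mean(q2s)
  })
}

#' Permutation test of OPLS-DA validity
#'
#' Refits the model under randomly permuted class labels and scores every
#' permutation with the same cross-validated Q2 as the observed model; the
#' p-value uses the add-one estimator
#' \code{p = (1 + #permuted Q2 >= observed) / (n + 1)}, so its floor is
#' \code{1/(n+1)}.
#'
#' @inheritParams cross_validate_q2
#' @param n_permutations number of label permutations (>= 1; the study
#'   design uses 2000).
#' @param cv_repeats CV repeats used for each Q2 evaluation.
#' @return list of class \code{permutation_result}: \code{n_permutations},
#'   \code{observed_q2}, \code{permuted_q2}, \code{p_value}.
#' @export
permutation_test <- function(x, classes, n_orthogonal = 1,
                             n_permutations = 2000, seed = 1,
                             cv_repeats = 3) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  X <- as_matrix_input(x)
  cc <- code_classes(classes)
  observed <- cross_validate_q2(X, classes, n_orthogonal,
                                n_repeats = cv_repeats,
                                seed = stage_seed(seed, "observed"))
  permuted <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm <- sample(cc$y)
      cross_validate_q2(X, factor(perm, levels = c(-1, 1)), n_orthogonal,
                        n_repeats = cv_repeats,
                        seed = sample.int(2^31 - 2, 1))
    }, numeric(1))
  })
  structure(list(n_permutations = n_permutations, observed_q2 = observed,
                 permuted_q2 = permuted,
                 p_value = (1 + sum(permuted >= observed)) /
                   (n_permutations + 1)),
            class = "permutation_result")
}

#' Correlation-coloured coefficient loadings
#'
#' For every feature, the covariance of the (scaled) feature with the
#' predictive score vector — the back-scaled coefficient plotted as line
#' height — paired with the feature-score Pearson correlation used as the
#' colour scale.  Zero-variance features map to (0, 0) with a warning.
#'
#' @param model a fitted \code{oplsda_model}.
#' @param x the feature matrix the model was fitted on.
#' @return data.frame with columns \code{covariance}, \code{correlation}
#'   (one row per feature).
#' @export
coefficient_loadings <- function(model, x) {
  X <- as_matrix_input(x)
  t_p <- model$predictive_scores
  if (nrow(X) != length(t_p) || ncol(X) != length(model$predictive_weights)) {
    stop("matrix shape does not match the fitted model", call. = FALSE)
  }
  n <- nrow(X)
  tc <- t_p - mean(t_p)
  Xc <- sweep(X, 2, colMeans(X))
  covv <- as.vector(crossprod(Xc, tc)) / (n - 1)
  sdx <- apply(X, 2, stats::sd)
  degenerate <- sdx == 0
  corr <- rep(0, ncol(X))
  ok <- !degenerate
  corr[ok] <- covv[ok] / (sdx[ok] * stats::sd(t_p))
  covv[degenerate] <- 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature(s) set to (0, 0)",
            call. = FALSE)
  }
  data.frame(covariance = covv, correlation = corr)
}
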