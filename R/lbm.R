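## Mass-univariate lesion-behavior mapping: partial Pearson
## correlations controlling covariates (log lesion volume by default),
## continuous family-wise error correction by permutation (v-th largest
## |t|; v = 1 is the classical max-statistic correction), and
## multivariate PLSR mapping.

#' Natural log lesion volume
#'
#' `log(voxelCount * voxelVolume)` in mm^3; the standard nuisance
#' covariate of lesion-deficit mapping.
#'
#' @param lesion integer vector of lesion voxel indices (or logical
#'   array).
#' @param grid a [BrainGrid].
#' @return scalar log volume.
#' @export
logLesionVolume <- function(lesion, grid) {
  nvox <- if (is.array(lesion)) sum(lesion != 0) else length(lesion)
  if (nvox == 0L) stop("empty lesion has no volume")
  log(nvox * grid@voxelSize^3)
}

#' Patients x voxels lesion indicator matrix
#'
#' @param cohort a [LesionCohort] (or list of voxel-index vectors plus a
#'   grid).
#' @param grid required when `cohort` is a plain list.
#' @return binary matrix over in-mask voxels; column names are the
#'   linear voxel indices.
#' @export
lesionMatrix <- function(cohort, grid = NULL) {
  if (is(cohort, "LesionCohort")) {
    grid <- cohort@grid
    les <- cohort@lesions
  } else les <- cohort
  stopifnot(!is.null(grid))
  inmask <- which(grid@mask)
  X <- matrix(0L, length(les), length(inmask))
  colnames(X) <- as.character(inmask)
  pos <- match(unlist(les, use.names = FALSE), inmask)
  row <- rep.int(seq_along(les), vapply(les, length, 1L))
  X[cbind(row, pos)] <- 1L
  X
}

## Group feature columns by their missing-row pattern so each group can
## be residualized and correlated in one matrix operation. Binary
## lesion matrices have a single (complete) group; fLNM feature
## matrices have NA inside each patient's own lesion.
naGroups <- function(X) {
  miss <- is.na(X)
  if (!any(miss)) return(list(list(cols = seq_len(ncol(X)),
                                   rows = seq_len(nrow(X)))))
  key <- apply(miss, 2L, function(z) paste(which(z), collapse = ","))
  lapply(split(seq_len(ncol(X)), key), function(cols) {
    bad <- which(miss[, cols[1L]])
    list(cols = cols, rows = setdiff(seq_len(nrow(X)), bad))
  })
}

## Residualize columns of M on [1, Z[rows, ]] restricted to rows.
residualize <- function(M, Z, rows) {
  D <- cbind(1, Z)[rows, , drop = FALSE]
  Q <- qr.Q(qr(D))
  Mr <- M[rows, , drop = FALSE]
  Mr - Q %*% crossprod(Q, Mr)
}

## Core engine: partial correlation of every feature column of X with
## every score column of Y given covariates Z, honoring per-column NA
## patterns of X. Returns list(r = features x scores, n = per-feature n).
partialCorEngine <- function(X, Y, Z) {
  Y <- as.matrix(Y)
  groups <- naGroups(X)
  r <- matrix(NA_real_, ncol(X), ncol(Y))
  nEff <- integer(ncol(X))
  for (g in groups) {
    Xr <- residualize(X[, g$cols, drop = FALSE], Z, g$rows)
    Yr <- residualize(Y, Z, g$rows)
    xs <- sqrt(colSums(Xr^2))
    ys <- sqrt(colSums(Yr^2))
    # a score with no variance left after partialling has no unique
    # association anywhere: r defined as 0
    yscale <- sqrt(colSums(scale(Y[g$rows, , drop = FALSE],
                                 scale = FALSE)^2))
    ydegen <- ys <= 1e-8 * pmax(yscale, 1)
    num <- crossprod(Xr, Yr)
    rg <- num / outer(xs, pmax(ys, .Machine$double.xmin))
    rg[xs == 0, ] <- NA_real_
    rg[, ydegen] <- 0
    r[g$cols, ] <- rg
    nEff[g$cols] <- length(g$rows)
  }
  list(r = r, n = nEff)
}

rToT <- function(r, n, c) {
  df <- n - 2 - c
  r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
}

## Feature filter. Binary features: lesioned in >= minLesion and
## <= n - minLesion patients. Continuous features: non-constant over
## observed rows with >= minObs observations (and, when nonZeroFilter,
## nonzero in >= minLesion patients, mirroring the voxel rule for
## disconnection edges).
filterFeatures <- function(X, minLesion, nCov, nonZeroFilter = FALSE) {
  n <- nrow(X)
  isBinary <- all(X[!is.na(X)] %in% c(0, 1))
  if (isBinary) {
    cs <- colSums(X, na.rm = TRUE)
    keep <- cs >= minLesion & cs <= n - minLesion
  } else {
    nObs <- colSums(!is.na(X))
    sds <- apply(X, 2L, function(v) stats::sd(v, na.rm = TRUE))
    keep <- nObs >= max(minLesion, nCov + 4L) & is.finite(sds) & sds > 0
    if (nonZeroFilter) {
      nz <- colSums(X != 0, na.rm = TRUE)
      keep <- keep & nz >= minLesion
    }
  }
  which(keep)
}

#' Voxelwise (feature-wise) partial correlation map
#'
#' Partial Pearson correlation between each feature (binary lesion
#' status, disconnection value, or connectivity T value) and a score,
#' controlling for covariates; returns an unthresholded signed map. A
#' lesion that lowers scores yields negative r.
#'
#' @param X patients x features matrix (binary or continuous; `NA`
#'   allowed in continuous features).
#' @param scores numeric vector, one score per patient.
#' @param covariates patients x c matrix (or `NULL`); log lesion volume
#'   in the standard analysis.
#' @param minLesion feature inclusion threshold: binary features must be
#'   lesioned in at least this many and at most n - minLesion patients.
#' @param nonZeroFilter require continuous features to be nonzero in at
#'   least `minLesion` patients (used for disconnection edges).
#' @param modality tag stored in the result.
#' @return an unthresholded [StatMap].
#' @export
voxelwisePartialCorr <- function(X, scores, covariates = NULL,
                                 minLesion = 4L, nonZeroFilter = FALSE,
                                 modality = "lbm") {
  stopifnot(nrow(X) == length(scores), all(is.finite(scores)))
  Z <- if (is.null(covariates)) matrix(0, nrow(X), 0)
       else as.matrix(covariates)
  keep <- filterFeatures(X, minLesion, ncol(Z), nonZeroFilter)
  if (!length(keep)) stop("no analyzable features after filtering")
  ids <- featureIdsOf(X, keep)
  pc <- partialCorEngine(X[, keep, drop = FALSE], scores, Z)
  r <- pc$r[, 1L]
  t <- rToT(r, pc$n, ncol(Z))
  new("StatMap", r = as.numeric(r), t = as.numeric(t),
      nEff = as.integer(pc$n), featureIds = ids,
      allFeatureIds = featureIdsOf(X, seq_len(ncol(X))),
      threshold = NA_real_, sigMask = logical(0), nPerm = 0L,
      alpha = NA_real_, v = 1L, nCovariates = ncol(Z),
      modality = modality)
}

featureIdsOf <- function(X, keep) {
  if (!is.null(colnames(X))) as.integer(colnames(X)[keep])
  else as.integer(keep)
}

#' Permutation family-wise error corrected map
#'
#' Continuous FWE correction: for each of `nPerm` permutations the
#' scores are permuted across patients (covariates stay aligned with
#' the lesions), the feature-wise partial-correlation t statistics are
#' recomputed, and the v-th largest |t| is recorded. The critical value
#' is the (1 - alpha) quantile (ceiling-index order statistic) of that
#' null distribution with the observed statistic included; `v = 1` is
#' the classical max-statistic correction controlling the probability
#' of a single false-positive feature.
#'
#' @inheritParams voxelwisePartialCorr
#' @param nPerm number of permutations (>= 100).
#' @param v voxel-count threshold (1 = max statistic).
#' @param alpha adjusted p threshold.
#' @param seed integer seed for the permutation stream.
#' @return a thresholded [StatMap].
#' @export
permutationFwe <- function(X, scores, covariates = NULL, nPerm = 1000L,
                           v = 1L, alpha = 0.05, seed,
                           minLesion = 4L, nonZeroFilter = FALSE,
                           modality = "lbm") {
  stopifnot(nPerm >= 100L, !missing(seed))
  obs <- voxelwisePartialCorr(X, scores, covariates, minLesion,
                              nonZeroFilter, modality)
  Z <- if (is.null(covariates)) matrix(0, nrow(X), 0)
       else as.matrix(covariates)
  keep <- match(obs@featureIds, featureIdsOf(X, seq_len(ncol(X))))
  Xk <- X[, keep, drop = FALSE]
  n <- nrow(Xk)
  Yperm <- withSeed(childSeed(seed, "fwe-perm"), {
    vapply(seq_len(nPerm), function(b) scores[sample.int(n)],
           numeric(n))
  })
  pc <- partialCorEngine(Xk, Yperm, Z)
  Tm <- rToT(pc$r, pc$n, ncol(Z))
  nullStats <- apply(abs(Tm), 2L, vthLargest, v = v)
  nullStats <- c(vthLargest(abs(obs@t), v), nullStats)
  B <- length(nullStats)
  threshold <- sort(nullStats)[ceiling((1 - alpha) * B)]
  new("StatMap", r = obs@r, t = obs@t, nEff = obs@nEff,
      featureIds = obs@featureIds, allFeatureIds = obs@allFeatureIds,
      threshold = threshold, sigMask = abs(obs@t) >= threshold,
      nPerm = as.integer(nPerm), alpha = alpha, v = as.integer(v),
      nCovariates = ncol(Z), modality = modality)
}

## PLS fit with the benign "standard deviation is zero" diagnostic
## (features constant within a CV fold) muffled; all other warnings
## propagate.
quietPls <- function(X, y, ncomp) {
  withCallingHandlers(
    mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                  scale = FALSE),
    warning = function(w) {
      if (grepl("standard deviation is zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Partial least squares regression map
#'
#' Multivariate mapping: the score is residualized on the covariates,
#' the PLS component count is chosen by repeated cross-validation
#' (predictive correlation criterion), the final model is fitted on the
#' full data, and variance explained is reported as the correlation
#' between full-model predictions and observed (residualized) scores.
#'
#' @inheritParams voxelwisePartialCorr
#' @param folds,repeats cross-validation design (default 5 x 5).
#' @param maxComponents largest component count tried.
#' @param seed integer seed for fold assignment.
#' @return list with `weights` (named by feature id), `nComponents`,
#'   `varianceExplained` (predicted-observed correlation), `cvCor`
#'   (mean CV predictive correlation per component count).
#' @export
plsrMap <- function(X, scores, covariates = NULL, folds = 5L,
                    repeats = 5L, maxComponents = 5L, seed,
                    minLesion = 4L, nonZeroFilter = FALSE) {
  stopifnot(maxComponents >= 1L, !missing(seed))
  Z <- if (is.null(covariates)) matrix(0, nrow(X), 0)
       else as.matrix(covariates)
  keep <- filterFeatures(X, minLesion, ncol(Z), nonZeroFilter)
  Xk <- X[, keep, drop = FALSE]
  Xk[is.na(Xk)] <- 0
  n <- nrow(Xk)
  y <- as.numeric(residualize(matrix(scores), Z, seq_len(n)))
  maxComponents <- min(maxComponents, n - ceiling(n / folds) - 1L,
                       ncol(Xk))

  cvPred <- matrix(NA_real_, n * repeats, maxComponents)
  cvObs <- numeric(n * repeats)
  withSeed(childSeed(seed, "plsr-cv"), {
    for (rep in seq_len(repeats)) {
      for (attempt in 1:10) {
        fold <- sample(rep_len(seq_len(folds), n))
        ok <- all(vapply(seq_len(folds), function(f)
          stats::sd(y[fold != f]) > 0, TRUE))
        if (ok) break
        warning("degenerate CV fold (constant response); refolding")
      }
      for (f in seq_len(folds)) {
        tr <- fold != f
        fit <- quietPls(Xk[tr, , drop = FALSE], y[tr],
                        ncomp = maxComponents)
        pr <- predict(fit, Xk[!tr, , drop = FALSE])$predict[, 1L, ]
        rows <- (rep - 1L) * n + which(!tr)
        cvPred[rows, ] <- pr
        cvObs[rows] <- y[!tr]
      }
    }
  })
  cvCor <- vapply(seq_len(maxComponents), function(k) {
    if (stats::sd(cvPred[, k]) == 0) 0
    else stats::cor(cvPred[, k], cvObs)
  }, 1.0)
  nComp <- which.max(cvCor)

  fit <- quietPls(Xk, y, ncomp = nComp)
  pr <- predict(fit, Xk)
  weights <- pr$B.hat[, 1L, nComp]
  names(weights) <- colnames(Xk) %||% as.character(keep)
  pred <- pr$predict[, 1L, nComp]
  list(weights = weights, nComponents = nComp,
       varianceExplained = if (stats::sd(pred) == 0) 0
                           else stats::cor(pred, y),
       cvCor = cvCor)
}
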