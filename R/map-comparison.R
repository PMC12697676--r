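## Spatial comparison of lesion-deficit maps between cognitive models.

#' Spatial correlation of two unthresholded maps
#'
#' Pearson correlation of the signed statistics over a common feature
#' set. Both maps must be defined on the identical feature mask so the
#' correlation uses the same number of values.
#'
#' @param mapA,mapB [StatMap] objects or plain numeric vectors.
#' @return Pearson r.
#' @export
spatialCorrelation <- function(mapA, mapB) {
  a <- if (is(mapA, "StatMap")) mapA@t else as.numeric(mapA)
  b <- if (is(mapB, "StatMap")) mapB@t else as.numeric(mapB)
  if (is(mapA, "StatMap") && is(mapB, "StatMap") &&
      !identical(mapA@featureIds, mapB@featureIds))
    stop("maps are defined on different feature masks")
  if (length(a) != length(b))
    stop("maps are defined on different feature masks")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("spatial correlation undefined for a constant map")
  stats::cor(a, b)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilizing transform of correlation
#' coefficients.
#'
#' @param r correlation(s), |r| < 1.
#' @return z value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("fisherZ requires |r| < 1")
  atanh(r)
}

#' Compare map inter-correlations between two cognitive models
#'
#' Computes all pairwise spatial correlations among the K domain maps
#' under each model, Fisher-transforms them, and tests the paired
#' differences `d = z_correlatedFactors - z_bifactor` with a
#' dependent-samples t statistic whose null distribution is built by
#' sign-flipping the paired differences (the exact permutation analogue
#' of a paired t test; the observed statistic is included in the null
#' set). The default alternative is one-sided: bifactor maps are less
#' spatially inter-correlated.
#'
#' @param mapsBifactor,mapsCorrelated named lists of [StatMap]s (or
#'   numeric vectors) over the same domains and feature mask.
#' @param nPerm sign-flip permutations.
#' @param seed integer seed.
#' @param alternative `"greater"` (default, directional) or
#'   `"two.sided"`.
#' @return a [MapComparisonResult].
#' @export
compareModelMaps <- function(mapsBifactor, mapsCorrelated, nPerm = 10000L,
                             seed, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(!missing(seed))
  K <- length(mapsBifactor)
  if (length(mapsCorrelated) != K)
    stop("both models must supply the same domains")
  doms <- names(mapsBifactor) %||% paste0("domain", seq_len(K))
  if (!is.null(names(mapsCorrelated)) &&
      !identical(sort(names(mapsCorrelated)), sort(doms)))
    stop("domain names differ between models")
  if (!is.null(names(mapsCorrelated)))
    mapsCorrelated <- mapsCorrelated[doms]
  if (K < 3L)
    warning("fewer than 3 pairs: permutation p is unreliable")

  corrMat <- function(maps) {
    M <- diag(1, K)
    dimnames(M) <- list(doms, doms)
    for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
      M[i, j] <- M[j, i] <- spatialCorrelation(maps[[i]], maps[[j]])
    M
  }
  Rb <- corrMat(mapsBifactor)
  Rc <- corrMat(mapsCorrelated)
  ut <- which(upper.tri(Rb), arr.ind = TRUE)
  zPairs <- data.frame(
    domainA = doms[ut[, 1L]], domainB = doms[ut[, 2L]],
    rBifactor = Rb[ut], rCorrelated = Rc[ut],
    zBifactor = fisherZ(Rb[ut]), zCorrelated = fisherZ(Rc[ut]))
  d <- zPairs$zCorrelated - zPairs$zBifactor
  sf <- signFlipPairedTest(d, nPerm = nPerm,
                           seed = childSeed(seed, "map-compare"),
                           alternative = alternative)

  new("MapComparisonResult", corrBifactor = Rb, corrCorrelated = Rc,
      zPairs = zPairs, tObserved = sf$t, pPerm = sf$p,
      nPerm = as.integer(nPerm), alternative = alternative)
}

#' Sign-flip permutation test of a dependent-samples t statistic
#'
#' Given paired differences `d`, computes `t = mean(d) / (sd(d) /
#' sqrt(m))` and builds the null by independently flipping the sign of
#' each pair; the observed statistic is included in the null set, so
#' under a sign-symmetric null `P(p <= alpha) <= alpha`. With a single
#' pair, `mean(d)` is used as the statistic.
#'
#' @param d numeric vector of paired differences.
#' @param nPerm number of random sign-flip assignments.
#' @param seed integer seed.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return list with `t` (observed statistic) and `p`.
#' @export
signFlipPairedTest <- function(d, nPerm = 10000L, seed,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(!missing(seed), length(d) >= 1L)
  m <- length(d)
  tstat <- function(x, s) {
    if (m < 2L) return(x)
    if (s == 0) 0 else x / (s / sqrt(m))
  }
  sdd <- if (m < 2L) 0 else stats::sd(d)
  tObs <- tstat(mean(d), sdd)
  tPerm <- withSeed(seed, {
    flips <- matrix(sample(c(-1, 1), m * nPerm, replace = TRUE), m)
    dp <- d * flips
    mu <- colMeans(dp)
    if (m < 2L) mu
    else {
      sdv <- sqrt(pmax(colMeans(dp^2) - mu^2, 0) * m / (m - 1))
      tp <- mu / (sdv / sqrt(m))
      tp[sdv == 0] <- 0
      tp
    }
  })
  stat <- if (alternative == "greater") tObs else abs(tObs)
  statPerm <- if (alternative == "greater") tPerm else abs(tPerm)
  list(t = tObs, p = (1 + sum(statPerm >= stat - 1e-12)) / (nPerm + 1))
}
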