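## Lesion network mapping: structural (streamline disconnection) and
## functional (normative connectivity seed maps), plus their
## mass-univariate group analyses.

#' Percent-disconnection matrix for one lesion
#'
#' A streamline counts as disconnected iff at least one of its voxels
#' lies in the lesion; entry (a, b) is 100 x disconnected / total
#' streamlines between parcels a and b. Parcel pairs without
#' streamlines stay 0.
#'
#' @param lesion integer vector of lesion voxel indices.
#' @param tractogram a [Tractogram].
#' @param parcellation the [Parcellation] the tractogram endpoints refer
#'   to.
#' @return P x P symmetric percent matrix with zero diagonal.
#' @export
disconnectionMatrix <- function(lesion, tractogram, parcellation) {
  P <- parcellation@nParcels
  if (tractogram@nParcels != P)
    stop("tractogram endpoints inconsistent with parcellation")
  nS <- length(tractogram@streamlines)
  inLesion <- tractogram@flatVox %in% lesion
  disc <- rowsum(as.numeric(inLesion), tractogram@flatId,
                 reorder = TRUE) > 0
  M <- matrix(0, P, P)
  eid <- tractogram@edgeId
  tot <- tapply(rep(1, nS), eid, sum)
  hit <- tapply(as.numeric(disc), eid, sum)
  pct <- 100 * hit / tot
  ep <- tractogram@endpoints[!duplicated(eid), , drop = FALSE]
  epOrder <- eid[!duplicated(eid)]
  ep <- ep[match(as.integer(names(tot)), epOrder), , drop = FALSE]
  M[ep] <- pct
  M[ep[, 2:1, drop = FALSE]] <- pct
  M
}

#' Upper-triangle edge features across patients
#'
#' Vectorizes each patient's disconnection matrix over the upper
#' triangle so every parcel-pair edge is tested once.
#'
#' @param matrices list of P x P disconnection matrices.
#' @return list with `X` (patients x edges), `edges` (two-column parcel
#'   pair matrix aligned with the columns).
#' @export
edgeFeatures <- function(matrices) {
  P <- nrow(matrices[[1L]])
  ut <- upper.tri(matrix(0, P, P))
  X <- t(vapply(matrices, function(m) m[ut], numeric(sum(ut))))
  edges <- cbind(row(diag(P))[ut], col(diag(P))[ut])
  colnames(X) <- seq_len(ncol(X))
  list(X = X, edges = edges)
}

#' Functional lesion network map for one lesion
#'
#' Per normative subject: the first principal component time course of
#' the within-lesion voxel series (sign-aligned with the mean seed
#' series) is correlated with every brain voxel and Fisher-z
#' transformed; across subjects a one-sample t is computed per voxel.
#' Voxels inside the seeding lesion are excluded from the target set
#' (`NA` in the result) because seed-target overlap is uninformative.
#'
#' @param lesion integer vector of lesion voxel indices.
#' @param normative a [NormativeFunctional].
#' @return a [FunctionalLesionMap].
#' @export
flnmMap <- function(lesion, normative) {
  seedCols <- which(normative@maskIdx %in% lesion)
  if (!length(seedCols))
    stop("lesion does not overlap the functional data mask")
  nV <- length(normative@maskIdx)
  Zs <- vapply(normative@series, function(S) {
    seed <- S[, seedCols, drop = FALSE]
    seedC <- sweep(seed, 2L, colMeans(seed))
    pc1 <- if (ncol(seedC) == 1L) seedC[, 1L]
           else svd(seedC, nu = 1L, nv = 0L)$u[, 1L]
    m <- rowMeans(seed)
    if (stats::cor(pc1, m) < 0) pc1 <- -pc1
    r <- colCor(pc1, S)
    r <- pmin(pmax(r, -0.999999), 0.999999)
    atanh(r)
  }, numeric(nV))
  m <- ncol(Zs)
  mu <- rowMeans(Zs)
  sdv <- apply(Zs, 1L, stats::sd)
  tv <- mu / (sdv / sqrt(m))
  tv[seedCols] <- NA_real_
  new("FunctionalLesionMap", values = tv, maskIdx = normative@maskIdx,
      nSubjects = as.integer(m))
}

#' Edgewise mass-univariate mapping of disconnection matrices
#'
#' Vectorizes the upper triangles and delegates to the same partial
#' correlation + permutation FWE machinery as voxelwise mapping. Edges
#' nonzero in fewer than `minLesion` patients are excluded.
#'
#' @param matrices list of per-patient disconnection matrices.
#' @param scores,covariates,nPerm,v,alpha,seed,minLesion see
#'   [permutationFwe()].
#' @return a [StatMap] over edges (feature ids index the upper-triangle
#'   enumeration; see [edgeFeatures()]).
#' @export
edgewiseMap <- function(matrices, scores, covariates = NULL,
                        nPerm = 1000L, v = 1L, alpha = 0.05, seed,
                        minLesion = 4L) {
  ef <- edgeFeatures(matrices)
  permutationFwe(ef$X, scores, covariates, nPerm = nPerm, v = v,
                 alpha = alpha, seed = seed, minLesion = minLesion,
                 nonZeroFilter = TRUE, modality = "slnm")
}

#' Voxelwise mapping of functional lesion network maps
#'
#' Stacks per-patient connectivity T values into a patients x voxels
#' matrix (`NA` inside each patient's own lesion; such voxels use the
#' patients observed there) and delegates to the partial correlation +
#' permutation FWE machinery with continuous features.
#'
#' @param maps list of [FunctionalLesionMap] objects, one per patient.
#' @param scores,covariates,nPerm,v,alpha,seed,minLesion see
#'   [permutationFwe()].
#' @return a [StatMap] over voxels (feature ids are linear voxel
#'   indices).
#' @export
voxelwiseFlnmMapping <- function(maps, scores, covariates = NULL,
                                 nPerm = 1000L, v = 1L, alpha = 0.05,
                                 seed, minLesion = 4L) {
  maskIdx <- maps[[1L]]@maskIdx
  X <- t(vapply(maps, function(m) {
    stopifnot(identical(m@maskIdx, maskIdx))
    m@values
  }, numeric(length(maskIdx))))
  colnames(X) <- as.character(maskIdx)
  permutationFwe(X, scores, covariates, nPerm = nPerm, v = v,
                 alpha = alpha, seed = seed, minLesion = minLesion,
                 modality = "flnm")
}
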