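#' Brain grid
#'
#' A low-resolution isotropic voxel grid (default 3 mm) with an
#' ellipsoidal brain mask and a voxel-to-world affine. All volumetric
#' objects in the package live on such a grid.
#'
#' @slot dims integer triple, voxels per axis.
#' @slot voxelSize isotropic voxel edge length in mm.
#' @slot mask logical 3D array, the brain mask.
#' @slot affine 4x4 voxel-to-world transform (RAS, 0-based voxel indices).
#' @exportClass BrainGrid
setClass("BrainGrid", representation(
  dims = "integer", voxelSize = "numeric", mask = "array",
  affine = "matrix"
), validity = function(object) {
  if (length(object@dims) != 3L) return("dims must have length 3")
  if (any(object@dims < 8L)) return("each grid dimension must be >= 8")
  if (!all(dim(object@mask) == object@dims)) return("mask/dims mismatch")
  if (!any(object@mask)) return("brain mask is empty")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  d <- try(det(object@affine), silent = TRUE)
  if (inherits(d, "try-error") || !is.finite(d) || d == 0)
    return("affine must be an invertible 4x4 matrix")
  TRUE
})

#' Parcellation of a brain grid
#'
#' Integer labels 1..P tiling the brain mask (0 = background), plus a
#' parcel-to-network assignment used by the normative functional
#' generator.
#'
#' @slot labels integer 3D array of parcel labels.
#' @slot nParcels number of parcels P.
#' @slot parcelNetworks integer vector of length P, network id per parcel.
#' @exportClass Parcellation
setClass("Parcellation", representation(
  labels = "array", nParcels = "integer", parcelNetworks = "integer"
), validity = function(object) {
  P <- object@nParcels
  tab <- tabulate(object@labels[object@labels > 0L], nbins = P)
  if (any(tab == 0L)) return("every parcel 1..P must occupy >= 1 voxel")
  if (length(object@parcelNetworks) != P)
    return("parcelNetworks must have one entry per parcel")
  TRUE
})

#' Normative tractogram
#'
#' Synthetic streamlines connecting parcel pairs; a stand-in for a
#' normative diffusion tractography atlas. Voxel paths are stored as
#' linear indices into the grid, with per-streamline endpoint parcel
#' pairs and a cached flat index used for fast lesion intersection.
#'
#' @slot streamlines list of integer vectors (linear voxel indices).
#' @slot endpoints integer matrix, one (a, b) parcel pair per row, a < b.
#' @slot edgeId integer vector mapping each streamline to its parcel-pair
#'   edge (upper-triangle enumeration).
#' @slot nParcels parcel count the endpoints refer to.
#' @slot flatVox,flatId concatenated voxel indices and their streamline
#'   ids (cache used by [disconnectionMatrix()]).
#' @exportClass Tractogram
setClass("Tractogram", representation(
  streamlines = "list", endpoints = "matrix", edgeId = "integer",
  nParcels = "integer", flatVox = "integer", flatId = "integer"
), validity = function(object) {
  if (nrow(object@endpoints) != length(object@streamlines))
    return("one endpoint pair per streamline required")
  if (length(object@streamlines) &&
      any(vapply(object@streamlines, length, 1L) < 2L))
    return("each streamline needs >= 2 voxels")
  TRUE
})

#' Normative resting-state functional data
#'
#' Per-subject voxel time series over the in-mask voxels, generated from
#' a shared-network-signal model; a stand-in for a normative functional
#' connectome.
#'
#' @slot series list of timepoints x in-mask-voxel matrices, one per
#'   subject.
#' @slot maskIdx linear voxel indices of the in-mask columns.
#' @slot networkLabels integer network id per in-mask voxel (ground truth).
#' @slot withinNetworkCorr generative within-network correlation.
#' @exportClass NormativeFunctional
setClass("NormativeFunctional", representation(
  series = "list", maskIdx = "integer", networkLabels = "integer",
  withinNetworkCorr = "numeric"
), validity = function(object) {
  if (!length(object@series)) return("need >= 1 subject")
  nv <- length(object@maskIdx)
  okdim <- vapply(object@series, function(m) ncol(m) == nv, TRUE)
  if (!all(okdim)) return("series columns must match maskIdx")
  TRUE
})

#' Simulation ground truth
#'
#' The generative parameters behind a synthetic cohort, exported so
#' recovery tests can compare estimates with truth.
#'
#' @slot loadings true tests x factors loading matrix.
#' @slot uniquenesses true residual variances per test.
#' @slot factorCov true factor covariance.
#' @slot anatomyEffects named list: per factor, a list with `voxels`
#'   (linear indices) and `effect` (score drop per fully lesioned
#'   anatomy).
#' @slot scores true patients x factors latent scores.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  loadings = "matrix", uniquenesses = "numeric", factorCov = "matrix",
  anatomyEffects = "list", scores = "matrix"
))

#' Synthetic patient cohort
#'
#' Binary lesion masks (stored sparsely as in-mask voxel index sets) and
#' a behavior table with missing entries, on a common [BrainGrid].
#'
#' @slot grid the underlying [BrainGrid].
#' @slot lesions list of integer vectors: linear voxel indices per
#'   patient lesion.
#' @slot behavior patients x tests numeric matrix, `NA` = missing.
#' @slot missingRate nominal fraction of deleted entries.
#' @slot patientIds character ids.
#' @exportClass LesionCohort
setClass("LesionCohort", representation(
  grid = "BrainGrid", lesions = "list", behavior = "matrix",
  missingRate = "numeric", patientIds = "character"
), validity = function(object) {
  if (length(object@lesions) != nrow(object@behavior))
    return("one lesion per behavior row required")
  if (any(vapply(object@lesions, length, 1L) == 0L))
    return("every lesion must be nonempty")
  inmask <- which(object@grid@mask)
  allv <- unlist(object@lesions, use.names = FALSE)
  if (length(allv) && !all(allv %in% inmask))
    return("lesion voxels must lie inside the brain mask")
  TRUE
})

#' Confirmatory factor model specification
#'
#' Declares which tests load on which factors, the factor covariance
#' structure, and any correlated-residual pairs. A bifactor spec has a
#' general factor loading on every test and orthogonal factors; a
#' correlated-factors spec has only group factors with free
#' inter-correlations.
#'
#' @slot tests,factors ordered names.
#' @slot pattern binary tests x factors matrix; 1 = free loading.
#' @slot factorCovStructure `"orthogonal"` or `"free"`.
#' @slot residualCovPairs character matrix with two columns naming test
#'   pairs whose residual covariance is free.
#' @exportClass FactorModelSpec
setClass("FactorModelSpec", representation(
  tests = "character", factors = "character", pattern = "matrix",
  factorCovStructure = "character", residualCovPairs = "matrix"
), validity = function(object) {
  if (!all(dim(object@pattern) == c(length(object@tests),
                                    length(object@factors))))
    return("pattern must be tests x factors")
  if (any(rowSums(object@pattern) < 1))
    return("every test must load on >= 1 factor")
  if (!object@factorCovStructure %in% c("orthogonal", "free"))
    return("factorCovStructure must be 'orthogonal' or 'free'")
  if (ncol(object@residualCovPairs) != 2L && nrow(object@residualCovPairs))
    return("residualCovPairs must have two columns")
  TRUE
})

#' Fitted confirmatory factor model
#'
#' @slot spec the [FactorModelSpec] that was fitted.
#' @slot loadings,uniquenesses,residualCov,factorCov,mu estimates.
#' @slot loglik,loglikSaturated maximized log-likelihoods.
#' @slot chiSquare,df likelihood-ratio statistic against the saturated
#'   model and its degrees of freedom.
#' @slot nUsed cases entering the likelihood.
#' @slot converged optimizer convergence flag.
#' @slot satSigma,satMu saturated-model (EM) estimates used for SRMR and
#'   residual diagnostics.
#' @slot se named list of standard errors (empty unless requested).
#' @slot estimator `"fiml"` or `"ml_complete"`.
#' @exportClass FittedFactorModel
setClass("FittedFactorModel", representation(
  spec = "FactorModelSpec", loadings = "matrix", uniquenesses = "numeric",
  residualCov = "matrix", factorCov = "matrix", mu = "numeric",
  loglik = "numeric", loglikSaturated = "numeric", chiSquare = "numeric",
  df = "numeric", nUsed = "integer", converged = "logical",
  satSigma = "matrix", satMu = "numeric", se = "list",
  estimator = "character"
), validity = function(object) {
  if (object@df < 0) return("negative degrees of freedom")
  if (any(object@uniquenesses < -1e-8))
    return("uniquenesses must be nonnegative")
  TRUE
})

#' Mass-univariate statistic map
#'
#' Signed per-feature statistics (partial r and t) over voxels or
#' edges, optionally with a permutation family-wise-error threshold and
#' significance mask.
#'
#' @slot r,t per-feature statistics (features retained by the filter).
#' @slot nEff effective n per feature (complete cases).
#' @slot featureIds identifiers of retained features (voxel linear
#'   indices, or edge ids).
#' @slot allFeatureIds identifiers of all candidate features before
#'   filtering.
#' @slot threshold critical |t| from the permutation null (`NA` if
#'   unthresholded).
#' @slot sigMask logical per retained feature.
#' @slot nPerm,alpha,v permutation settings.
#' @slot nCovariates number of covariates partialled out.
#' @slot modality free-text tag ("lbm", "slnm", "flnm", ...).
#' @exportClass StatMap
setClass("StatMap", representation(
  r = "numeric", t = "numeric", nEff = "integer", featureIds = "integer",
  allFeatureIds = "integer", threshold = "numeric", sigMask = "logical",
  nPerm = "integer", alpha = "numeric", v = "integer",
  nCovariates = "integer", modality = "character"
), validity = function(object) {
  k <- length(object@r)
  if (length(object@t) != k || length(object@featureIds) != k)
    return("r, t and featureIds must align")
  if (length(object@sigMask) && length(object@sigMask) != k)
    return("sigMask must align with features")
  if (length(object@sigMask) && !is.na(object@threshold) &&
      !is.finite(object@threshold))
    return("threshold must be finite when maps are thresholded")
  TRUE
})

#' Per-patient functional lesion network map
#'
#' Voxelwise T values of normative connectivity seeded by one lesion;
#' `NA` inside the seeding lesion (seed-target overlap is excluded).
#'
#' @slot values T value per in-mask voxel.
#' @slot maskIdx linear indices of the in-mask voxels.
#' @slot nSubjects normative subjects entering the one-sample t.
#' @exportClass FunctionalLesionMap
setClass("FunctionalLesionMap", representation(
  values = "numeric", maskIdx = "integer", nSubjects = "integer"
))

#' Model-map comparison result
#'
#' Spatial correlation matrices of domain maps under two cognitive
#' models, their Fisher-z paired differences, and the sign-flip
#' permutation test of the dependent-samples t statistic.
#'
#' @slot corrBifactor,corrCorrelated K x K spatial correlation matrices.
#' @slot zPairs data.frame of matched pairs with both models' r and z.
#' @slot tObserved dependent-samples t on paired z differences
#'   (correlated-factors minus bifactor).
#' @slot pPerm permutation p value.
#' @slot nPerm permutations used.
#' @slot alternative `"greater"` (bifactor less inter-correlated) or
#'   `"two.sided"`.
#' @exportClass MapComparisonResult
setClass("MapComparisonResult", representation(
  corrBifactor = "matrix", corrCorrelated = "matrix", zPairs = "data.frame",
  tObserved = "numeric", pPerm = "numeric", nPerm = "integer",
  alternative = "character"
), validity = function(object) {
  if (object@pPerm <= 0 || object@pPerm > 1)
    return("pPerm must lie in (0, 1]")
  TRUE
})
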