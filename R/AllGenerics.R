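#' @name accessors
#' @title Accessors for gLDM classes
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param x an object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))
#' @rdname accessors
#' @export
setGeneric("behavior", function(x) standardGeneric("behavior"))
#' @rdname accessors
#' @export
setGeneric("lesions", function(x) standardGeneric("lesions"))
#' @rdname accessors
#' @export
setGeneric("brainGrid", function(x) standardGeneric("brainGrid"))
#' @rdname accessors
#' @export
setGeneric("factorLoadings", function(x) standardGeneric("factorLoadings"))
#' @rdname accessors
#' @export
setGeneric("uniquenesses", function(x) standardGeneric("uniquenesses"))
#' @rdname accessors
#' @export
setGeneric("factorCov", function(x) standardGeneric("factorCov"))
#' @rdname accessors
#' @export
setGeneric("chiSquare", function(x) standardGeneric("chiSquare"))
#' @rdname accessors
#' @export
setGeneric("dof", function(x) standardGeneric("dof"))
#' @rdname accessors
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))
#' @rdname accessors
#' @export
setGeneric("sigFeatures", function(x) standardGeneric("sigFeatures"))

#' @rdname accessors
setMethod("nPatients", "LesionCohort", function(x) nrow(x@behavior))
#' @rdname accessors
setMethod("behavior", "LesionCohort", function(x) x@behavior)
#' @rdname accessors
setMethod("lesions", "LesionCohort", function(x) x@lesions)
#' @rdname accessors
setMethod("brainGrid", "LesionCohort", function(x) x@grid)
#' @rdname accessors
setMethod("factorLoadings", "FittedFactorModel", function(x) x@loadings)
#' @rdname accessors
setMethod("uniquenesses", "FittedFactorModel", function(x) x@uniquenesses)
#' @rdname accessors
setMethod("factorCov", "FittedFactorModel", function(x) x@factorCov)
#' @rdname accessors
setMethod("chiSquare", "FittedFactorModel", function(x) x@chiSquare)
#' @rdname accessors
setMethod("dof", "FittedFactorModel", function(x) x@df)
#' @rdname accessors
setMethod("tValues", "StatMap", function(x) x@t)
#' @rdname accessors
setMethod("sigFeatures", "StatMap", function(x) {
  if (!length(x@sigMask)) integer(0) else x@featureIds[x@sigMask]
})

setMethod("show", "BrainGrid", function(object) {
  cat(sprintf("BrainGrid %dx%dx%d @ %g mm, %d in-mask voxels\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@voxelSize, sum(object@mask)))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d parcels, %d networks\n", object@nParcels,
              length(unique(object@parcelNetworks))))
})

setMethod("show", "Tractogram", function(object) {
  cat(sprintf("Tractogram: %d streamlines over %d parcel-pair edges\n",
              length(object@streamlines), length(unique(object@edgeId))))
})

setMethod("show", "NormativeFunctional", function(object) {
  cat(sprintf(
    "NormativeFunctional: %d subjects x %d timepoints x %d voxels (w = %g)\n",
    length(object@series), nrow(object@series[[1]]),
    length(object@maskIdx), object@withinNetworkCorr))
})

setMethod("show", "LesionCohort", function(object) {
  cat(sprintf(
    "LesionCohort: %d patients, %d tests, %.1f%% entries missing\n",
    nrow(object@behavior), ncol(object@behavior),
    100 * mean(is.na(object@behavior))))
})

setMethod("show", "FactorModelSpec", function(object) {
  cat(sprintf("FactorModelSpec: %d tests, %d factors (%s), %d residual pairs\n",
              length(object@tests), length(object@factors),
              object@factorCovStructure, nrow(object@residualCovPairs)))
})

setMethod("show", "FittedFactorModel", function(object) {
  cat(sprintf(
    "FittedFactorModel (%s): chi^2(%d) = %.2f, n = %d, %s\n",
    object@estimator, object@df, object@chiSquare, object@nUsed,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "StatMap", function(object) {
  thr <- if (is.na(object@threshold)) "unthresholded"
         else sprintf("|t| >= %.3f, %d significant", object@threshold,
                      sum(object@sigMask))
  cat(sprintf("StatMap [%s]: %d features, %s\n", object@modality,
              length(object@r), thr))
})

setMethod("show", "MapComparisonResult", function(object) {
  cat(sprintf(
    "MapComparisonResult: t = %.3f over %d pairs, permutation p = %.4g (%s)\n",
    object@tObserved, nrow(object@zPairs), object@pPerm,
    object@alternative))
})
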