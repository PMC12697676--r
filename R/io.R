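## File formats: NIfTI volumes (RNifti), TSV tables, JSON-lines
## tractograms, JSON model reports. Voxel indices are written 0-based;
## in-memory R objects use 1-based linear indices.

#' Write a volume as NIfTI
#'
#' @param arr 3D (or 4D) array on the grid.
#' @param grid a [BrainGrid] supplying the affine.
#' @param file output path (`.nii.gz`).
#' @return the file path, invisibly.
#' @export
writeVolume <- function(arr, grid, file) {
  img <- RNifti::asNifti(arr)
  RNifti::qform(img) <- structure(grid@affine, code = 2L)
  RNifti::sform(img) <- structure(grid@affine, code = 2L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI volume as a plain array
#' @param file path to a NIfTI file.
#' @return numeric array.
#' @export
readVolume <- function(file) {
  if (!file.exists(file)) stop("missing upstream artifact: ", file)
  arr <- RNifti::readNifti(file)
  array(as.numeric(arr), dim = dim(arr))
}

writeTsv <- function(x, file) {
  utils::write.table(format(as.data.frame(x), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

readTsv <- function(file) {
  if (!file.exists(file)) stop("missing upstream artifact: ", file)
  utils::read.delim(file, check.names = FALSE)
}

writeJson <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Write a cohort's lesions as a 4D NIfTI stack
#' @param cohort a [LesionCohort].
#' @param file output `.nii.gz` path.
#' @return the path, invisibly.
#' @export
writeLesionStack <- function(cohort, file) {
  dims <- cohort@grid@dims
  n <- nPatients(cohort)
  arr <- array(0L, c(dims, n))
  stride <- prod(dims)
  for (i in seq_len(n))
    arr[cohort@lesions[[i]] + (i - 1L) * stride] <- 1L
  writeVolume(arr, cohort@grid, file)
}

#' Read a 4D lesion stack into a list of voxel-index vectors
#' @param file path written by [writeLesionStack()].
#' @return list with `lesions` (list of integer vectors) and `dims`.
#' @export
readLesionStack <- function(file) {
  arr <- readVolume(file)
  d <- dim(arr)
  stride <- prod(d[1:3])
  lesions <- lapply(seq_len(d[4]), function(i) {
    which(arr[, , , i] != 0)
  })
  list(lesions = lesions, dims = d[1:3])
}

#' Write a tractogram as JSON lines
#'
#' One record per streamline: endpoint parcel pair and the voxel path
#' as 0-based (i, j, k) triples.
#'
#' @param tractogram a [Tractogram].
#' @param grid the [BrainGrid] the voxel indices refer to.
#' @param file output `.jsonl` path.
#' @return the path, invisibly.
#' @export
writeTractogramJsonl <- function(tractogram, grid, file) {
  dims <- grid@dims
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(tractogram@streamlines)) {
    ijk <- arrayInd(tractogram@streamlines[[i]], dims) - 1L
    rec <- list(a = tractogram@endpoints[i, 1L],
                b = tractogram@endpoints[i, 2L],
                vox = unname(split(ijk, row(ijk))))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(file)
}

#' Read a JSON-lines tractogram
#' @param file path written by [writeTractogramJsonl()].
#' @param grid the [BrainGrid] for index conversion.
#' @param nParcels parcel count of the referenced parcellation.
#' @return a [Tractogram].
#' @export
readTractogramJsonl <- function(file, grid, nParcels) {
  if (!file.exists(file)) stop("missing upstream artifact: ", file)
  lines <- readLines(file)
  dims <- grid@dims
  P <- as.integer(nParcels)
  streamlines <- vector("list", length(lines))
  endpoints <- matrix(0L, length(lines), 2L)
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyMatrix = TRUE)
    ijk <- matrix(as.integer(unlist(rec$vox)), ncol = 3L, byrow = TRUE) + 1L
    streamlines[[i]] <- ijk[, 1L] + dims[1L] * (ijk[, 2L] - 1L) +
      dims[1L] * dims[2L] * (ijk[, 3L] - 1L)
    endpoints[i, ] <- c(rec$a, rec$b)
  }
  a <- endpoints[, 1L]; b <- endpoints[, 2L]
  new("Tractogram", streamlines = streamlines, endpoints = endpoints,
      edgeId = as.integer((a - 1L) * P - (a * (a - 1L)) %/% 2L + (b - a)),
      nParcels = P,
      flatVox = as.integer(unlist(streamlines, use.names = FALSE)),
      flatId = rep.int(seq_along(streamlines),
                       vapply(streamlines, length, 1L)))
}

#' Serialize a fitted factor model to JSON
#'
#' @param model a [FittedFactorModel].
#' @param indices optional output of [fitIndices()].
#' @param omega optional output of [omegaHierarchical()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeModelJson <- function(model, indices = NULL, omega = NULL, file) {
  writeJson(list(
    estimator = model@estimator,
    tests = model@spec@tests, factors = model@spec@factors,
    loadings = apply(model@loadings, 1L, function(r) as.list(r)),
    uniquenesses = as.list(model@uniquenesses),
    factorCov = model@factorCov,
    means = as.list(model@mu),
    loglik = model@loglik, loglikSaturated = model@loglikSaturated,
    chiSquare = model@chiSquare, df = model@df, nUsed = model@nUsed,
    converged = model@converged,
    fitIndices = if (!is.null(indices)) as.list(indices),
    omegaHierarchical = if (!is.null(omega)) as.list(omega)), file)
}

#' Write a statistic map as TSV (+ NIfTI volumes for voxel maps)
#'
#' The TSV holds one row per analyzed feature (id, r, t, n,
#' significant); the JSON sidecar records the threshold and permutation
#' settings. Voxel maps additionally get unthresholded r and t volumes
#' and a significance-mask volume.
#'
#' @param map a [StatMap].
#' @param prefix output path prefix.
#' @param grid [BrainGrid] (needed for voxel modalities).
#' @param edges optional two-column parcel-pair matrix aligned with the
#'   upper-triangle edge enumeration (for edge maps).
#' @return vector of files written, invisibly.
#' @export
writeStatMap <- function(map, prefix, grid = NULL, edges = NULL) {
  files <- character(0)
  tab <- data.frame(feature = map@featureIds, r = map@r, t = map@t,
                    n = map@nEff,
                    significant = if (length(map@sigMask)) map@sigMask
                                  else NA)
  if (!is.null(edges)) {
    tab$parcelA <- edges[map@featureIds, 1L]
    tab$parcelB <- edges[map@featureIds, 2L]
  }
  f <- paste0(prefix, ".tsv"); writeTsv(tab, f); files <- c(files, f)
  sidecar <- list(modality = map@modality, nFeatures = length(map@r),
                  threshold = map@threshold, nPerm = map@nPerm,
                  alpha = map@alpha, v = map@v,
                  nCovariates = map@nCovariates)
  f <- paste0(prefix, ".json"); writeJson(sidecar, f)
  files <- c(files, f)
  if (!is.null(grid) && map@modality %in% c("lbm", "flnm")) {
    for (what in c("r", "t", "sig")) {
      arr <- array(0, grid@dims)
      vals <- switch(what, r = map@r, t = map@t,
                     sig = as.numeric(map@sigMask))
      if (what == "sig" && !length(map@sigMask)) next
      arr[map@featureIds] <- vals
      f <- paste0(prefix, "_", what, ".nii.gz")
      writeVolume(arr, grid, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
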