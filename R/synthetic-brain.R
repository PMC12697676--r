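## Synthetic brain world: grid, parcellation, tractogram, normative
## functional data. Everything is a pure function of (config, seed).

#' Build a synthetic brain grid with parcellation and networks
#'
#' Creates an ellipsoidal brain mask on an isotropic voxel grid,
#' tiles the mask with `nParcels` contiguous parcels (Voronoi cells of
#' randomly placed in-mask seed voxels; cells of a convex mask are
#' connected), and groups parcels into `nNetworks` spatially coherent
#' networks by k-means on parcel centroids.
#'
#' @param dims integer triple, voxels per axis (each >= 8).
#' @param voxelSize isotropic voxel size in mm (default 3, the working
#'   resolution for lesion-deficit mapping).
#' @param nParcels number of gray-matter parcels (>= 4).
#' @param nNetworks number of functional networks (>= 2).
#' @param seed integer seed; same seed gives bit-identical output.
#' @return list with elements `grid` ([BrainGrid]), `parcellation`
#'   ([Parcellation]) and `networks` (integer 3D array of network labels,
#'   0 outside the mask).
#' @export
makeBrain <- function(dims, voxelSize = 3, nParcels = 20, nNetworks = 5,
                      seed) {
  stopifnot(nParcels >= 4, nNetworks >= 2, !missing(seed))
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 8L))
    stop("dims must be a triple with each entry >= 8")

  centre <- (dims + 1) / 2
  ax <- 0.45 * dims
  cx <- slice.index(array(0, dims), 1L)
  cy <- slice.index(array(0, dims), 2L)
  cz <- slice.index(array(0, dims), 3L)
  mask <- ((cx - centre[1]) / ax[1])^2 + ((cy - centre[2]) / ax[2])^2 +
    ((cz - centre[3]) / ax[3])^2 <= 1
  inmask <- which(mask)
  if (length(inmask) < 2L * nParcels)
    stop("grid too small to host ", nParcels, " parcels")

  affine <- diag(c(rep(voxelSize, 3), 1))
  affine[1:3, 4] <- -voxelSize * (dims - 1) / 2
  grid <- new("BrainGrid", dims = dims, voxelSize = voxelSize,
              mask = mask, affine = affine)

  coords <- cbind(cx[inmask], cy[inmask], cz[inmask])
  withSeed(childSeed(seed, "brain"), {
    seeds <- sample(length(inmask), nParcels)
    d2 <- matrix(0, length(inmask), nParcels)
    for (j in seq_len(nParcels))
      d2[, j] <- colSums((t(coords) - coords[seeds[j], ])^2)
    lab <- max.col(-d2, ties.method = "first")
    labels <- array(0L, dims)
    labels[inmask] <- lab

    centroids <- apply(coords, 2, function(v) tapply(v, lab, mean))
    km <- stats::kmeans(centroids, centers = min(nNetworks, nParcels),
                        nstart = 5, iter.max = 50)
    parcelNetworks <- as.integer(km$cluster)
  })

  parc <- new("Parcellation", labels = labels,
              nParcels = as.integer(nParcels),
              parcelNetworks = parcelNetworks)
  networks <- array(0L, dims)
  networks[inmask] <- parcelNetworks[lab]
  list(grid = grid, parcellation = parc, networks = networks)
}

#' Generate a synthetic normative tractogram
#'
#' For a random subset of parcel pairs (fraction `edgeDensity` of all
#' C(P,2) pairs), draws `nPerEdge` streamlines per pair as jittered
#' straight voxel paths between random voxels of the two parcels,
#' clipped to the brain mask. A stand-in for a normative streamline
#' atlas.
#'
#' @param grid a [BrainGrid].
#' @param parcellation a [Parcellation] on that grid.
#' @param nPerEdge streamlines per selected parcel pair.
#' @param edgeDensity fraction of parcel pairs connected, in (0, 1].
#' @param seed integer seed.
#' @return a [Tractogram].
#' @export
makeTractogram <- function(grid, parcellation, nPerEdge = 5,
                           edgeDensity = 1, seed) {
  stopifnot(edgeDensity > 0, edgeDensity <= 1, nPerEdge >= 1,
            !missing(seed))
  P <- parcellation@nParcels
  pairs <- t(utils::combn(P, 2L))
  dims <- grid@dims
  labels <- parcellation@labels
  parcVox <- split(which(labels > 0L), labels[labels > 0L])

  withSeed(childSeed(seed, "tract"), {
    nsel <- max(1L, round(edgeDensity * nrow(pairs)))
    sel <- if (nsel == nrow(pairs)) seq_len(nrow(pairs))
           else sort(sample(nrow(pairs), nsel))
    pairs <- pairs[sel, , drop = FALSE]

    streamlines <- vector("list", nrow(pairs) * nPerEdge)
    endpoints <- matrix(0L, length(streamlines), 2L)
    edgeId <- integer(length(streamlines))
    k <- 0L
    for (e in seq_len(nrow(pairs))) {
      a <- pairs[e, 1L]; b <- pairs[e, 2L]
      va <- parcVox[[a]]; vb <- parcVox[[b]]
      for (s in seq_len(nPerEdge)) {
        p0 <- arrayInd(va[sample.int(length(va), 1L)], dims)
        p1 <- arrayInd(vb[sample.int(length(vb), 1L)], dims)
        nstep <- max(2L, ceiling(sqrt(sum((p1 - p0)^2))) + 1L)
        tt <- seq(0, 1, length.out = nstep)
        path <- outer(tt, as.numeric(p1 - p0)) +
          matrix(as.numeric(p0), nstep, 3L, byrow = TRUE)
        if (nstep > 2L) {
          jit <- matrix(rnorm(3L * (nstep - 2L), sd = 0.7), ncol = 3L)
          path[2:(nstep - 1L), ] <- path[2:(nstep - 1L), ] + jit
        }
        path <- round(path)
        path <- pmin(pmax(path, 1), matrix(dims, nstep, 3L, byrow = TRUE))
        vox <- path[, 1L] + dims[1L] * (path[, 2L] - 1L) +
          dims[1L] * dims[2L] * (path[, 3L] - 1L)
        vox <- as.integer(vox[!duplicated(vox)])
        vox <- vox[grid@mask[vox]]
        # endpoints must sit in their parcels exactly
        v0 <- as.integer(p0[1] + dims[1] * (p0[2] - 1) +
                           dims[1] * dims[2] * (p0[3] - 1))
        v1 <- as.integer(p1[1] + dims[1] * (p1[2] - 1) +
                           dims[1] * dims[2] * (p1[3] - 1))
        vox <- vox[!(vox %in% c(v0, v1))]
        vox <- c(v0, vox, v1)
        k <- k + 1L
        streamlines[[k]] <- vox
        endpoints[k, ] <- c(a, b)
        edgeId[k] <- (a - 1L) * P - (a * (a - 1L)) %/% 2L + (b - a)
      }
    }
  })

  new("Tractogram", streamlines = streamlines, endpoints = endpoints,
      edgeId = edgeId, nParcels = P,
      flatVox = unlist(streamlines, use.names = FALSE),
      flatId = rep.int(seq_along(streamlines),
                       vapply(streamlines, length, 1L)))
}

#' Generate synthetic normative resting-state data
#'
#' Per subject, each in-mask voxel's time series is
#' `sqrt(w) * networkSignal + sqrt(1 - w) * noise`, so the expected
#' correlation between two voxels of the same network is `w` and
#' (asymptotically) 0 across networks. A stand-in for a normative
#' resting-state functional connectome.
#'
#' @param grid a [BrainGrid].
#' @param networks integer 3D array of network labels (from
#'   [makeBrain()]).
#' @param nSubjects normative subjects to simulate.
#' @param nTimepoints timepoints per subject (>= 50).
#' @param withinNetworkCorr target within-network voxel-pair
#'   correlation, in (0, 1).
#' @param seed integer seed.
#' @return a [NormativeFunctional].
#' @export
makeNormativeFunctional <- function(grid, networks, nSubjects = 15,
                                    nTimepoints = 150,
                                    withinNetworkCorr = 0.4, seed) {
  stopifnot(withinNetworkCorr > 0, withinNetworkCorr < 1,
            nTimepoints >= 50, !missing(seed))
  maskIdx <- which(grid@mask)
  lab <- as.integer(networks[maskIdx])
  nets <- sort(unique(lab))
  w <- withinNetworkCorr
  series <- withSeed(childSeed(seed, "func"), {
    lapply(seq_len(nSubjects), function(s) {
      sig <- matrix(rnorm(nTimepoints * length(nets)), nTimepoints)
      colnames(sig) <- as.character(nets)
      noise <- matrix(rnorm(nTimepoints * length(maskIdx)), nTimepoints)
      sqrt(w) * sig[, as.character(lab), drop = FALSE] +
        sqrt(1 - w) * noise
    })
  })
  new("NormativeFunctional", series = series, maskIdx = maskIdx,
      networkLabels = lab, withinNetworkCorr = w)
}
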