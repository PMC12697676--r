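## Synthetic cohort: lesions, ground-truth latent structure, behavior.

#' Default neuropsychological test battery
#'
#' The 23-test battery used throughout: WAIS subtests, aphasia and
#' naming measures, trail-making and coding speed tests, visuospatial
#' judgment and construction tests, and auditory-verbal list learning,
#' grouped into five cognitive domains (crystallized knowledge, verbal
#' learning/memory, processing speed, visuospatial ability, language).
#'
#' @return data.frame with columns `test` and `domain`.
#' @export
defaultTestBattery <- function() {
  data.frame(
    test = c("dig", "sim", "info", "ari", "wrat",
             "bnt", "tok", "sr", "cowa",
             "tmta", "tmtb", "cod", "ss",
             "bd", "mr", "cftc", "face", "jlo", "vrtc",
             "rey5", "reyr", "reyh", "cftr"),
    domain = c("language", "crystallized", "crystallized", "crystallized",
               "crystallized",
               "language", "language", "language", "language",
               "speed", "speed", "speed", "speed",
               "visuospatial", "visuospatial", "visuospatial",
               "visuospatial", "visuospatial", "visuospatial",
               "memory", "memory", "memory", "memory"),
    stringsAsFactors = FALSE
  )
}

#' Residual covariance pairs freed in the default models
#'
#' Copy/recall forms of the same figure and the two trail-making parts
#' share method variance beyond their factors.
#' @return two-column character matrix of test pairs.
#' @export
defaultResidualPairs <- function() {
  rbind(c("cftc", "cftr"), c("tmta", "tmtb"))
}

#' Construct a bifactor model specification
#'
#' Every test loads on a general factor `g` and on its domain factor;
#' all factors are mutually orthogonal.
#'
#' @param battery data.frame with `test` and `domain` columns
#'   (default [defaultTestBattery()]).
#' @param residualPairs two-column matrix of correlated-residual test
#'   pairs (default [defaultResidualPairs()]; use `NULL` for none).
#' @return a [FactorModelSpec].
#' @export
bifactorSpec <- function(battery = defaultTestBattery(),
                         residualPairs = defaultResidualPairs()) {
  domains <- unique(battery$domain)
  factors <- c("g", domains)
  pattern <- matrix(0, nrow(battery), length(factors),
                    dimnames = list(battery$test, factors))
  pattern[, "g"] <- 1
  pattern[cbind(seq_len(nrow(battery)), match(battery$domain, factors))] <- 1
  new("FactorModelSpec", tests = battery$test, factors = factors,
      pattern = pattern, factorCovStructure = "orthogonal",
      residualCovPairs = residualPairs %||% matrix(character(0), 0, 2))
}

#' Construct a correlated-factors model specification
#'
#' Domain factors only (no general factor), with free inter-factor
#' correlations, so g-associated variance stays embedded within each
#' domain factor.
#'
#' @inheritParams bifactorSpec
#' @return a [FactorModelSpec].
#' @export
correlatedFactorsSpec <- function(battery = defaultTestBattery(),
                                  residualPairs = defaultResidualPairs()) {
  domains <- unique(battery$domain)
  pattern <- matrix(0, nrow(battery), length(domains),
                    dimnames = list(battery$test, domains))
  pattern[cbind(seq_len(nrow(battery)), match(battery$domain, domains))] <- 1
  new("FactorModelSpec", tests = battery$test, factors = domains,
      pattern = pattern, factorCovStructure = "free",
      residualCovPairs = residualPairs %||% matrix(character(0), 0, 2))
}

#' Default generative ground-truth parameters
#'
#' Standardized bifactor truth: every test loads 0.6 on g and 0.45 on
#' its domain factor; uniquenesses complete each test's variance to 1.
#'
#' @param battery test battery data.frame.
#' @param gLoading,domainLoading true standardized loadings.
#' @return list with `loadings` (tests x factors), `uniquenesses` and
#'   `factorCov` (identity: generative factors are orthogonal).
#' @export
defaultGroundTruthParams <- function(battery = defaultTestBattery(),
                                     gLoading = 0.6,
                                     domainLoading = 0.45) {
  spec <- bifactorSpec(battery, NULL)
  L <- spec@pattern
  L[, "g"] <- gLoading * L[, "g"]
  L[, colnames(L) != "g"] <- domainLoading * L[, colnames(L) != "g"]
  u <- 1 - rowSums(L^2)
  stopifnot(all(u > 0))
  list(loadings = L, uniquenesses = stats::setNames(u, battery$test),
       factorCov = diag(ncol(L)))
}

#' Plant lesion-deficit anatomy for each factor
#'
#' Assigns each requested factor a small spherical brain region (around
#' the centroid of a dedicated parcel, regions mutually disjoint) and an
#' effect size: a patient's latent score on that factor drops by
#' `effect * fractionOfRegionLesioned`.
#'
#' @param brain output of [makeBrain()].
#' @param factors named numeric vector of effect sizes (name = factor;
#'   factors absent from the vector get no anatomy). Effects of 0 are
#'   kept with empty influence.
#' @param radius region radius in voxels.
#' @param nParcelsPerFactor parcels whose centroids seed each factor's
#'   region (g is often given a larger share).
#' @param parcels optional named list (factor -> parcel ids) pinning
#'   each factor's region to specific parcels, e.g. to place domain
#'   anatomies in distinct functional networks; unnamed factors fall
#'   back to random assignment.
#' @param seed integer seed.
#' @return named list per factor: `voxels` (linear indices), `effect`.
#' @export
planAnatomy <- function(brain, factors, radius = 2.2,
                        nParcelsPerFactor = NULL, parcels = NULL, seed) {
  stopifnot(!missing(seed))
  grid <- brain$grid
  parc <- brain$parcellation
  dims <- grid@dims
  P <- parc@nParcels
  nper <- nParcelsPerFactor %||%
    stats::setNames(rep(1L, length(factors)), names(factors))
  needed <- sum(nper[names(factors)])
  if (needed > P) stop("not enough parcels to host anatomy regions")

  inmask <- which(parc@labels > 0L)
  lab <- parc@labels[inmask]
  co <- arrayInd(inmask, dims)
  centroids <- apply(co, 2, function(v) tapply(v, lab, mean))

  pinned <- unlist(parcels, use.names = FALSE)
  if (length(pinned) && any(!pinned %in% seq_len(P)))
    stop("pinned parcels outside 1..P")
  withSeed(childSeed(seed, "anatomy"), {
    pool <- setdiff(sample(P), pinned)
  })
  assign <- list()
  k <- 0L
  for (f in names(factors)) {
    if (!is.null(parcels[[f]])) {
      assign[[f]] <- parcels[[f]]
    } else {
      assign[[f]] <- pool[(k + 1L):(k + nper[[f]])]
      k <- k + nper[[f]]
    }
  }
  if (anyNA(unlist(assign)))
    stop("not enough parcels to host anatomy regions")
  out <- vector("list", length(factors))
  names(out) <- names(factors)
  allco <- arrayInd(which(grid@mask), dims)
  allidx <- which(grid@mask)
  for (f in names(factors)) {
    ctr <- centroids[assign[[f]], , drop = FALSE]
    vox <- integer(0)
    for (i in seq_len(nrow(ctr))) {
      d2 <- colSums((t(allco) - ctr[i, ])^2)
      vox <- c(vox, allidx[d2 <= radius^2])
    }
    out[[f]] <- list(voxels = sort(unique(vox)), effect = factors[[f]])
  }
  # enforce disjoint regions: first-come ownership
  seen <- integer(0)
  for (f in names(out)) {
    out[[f]]$voxels <- setdiff(out[[f]]$voxels, seen)
    seen <- c(seen, out[[f]]$voxels)
  }
  out
}

#' Sample random blob lesions
#'
#' Each lesion is the union of 1-3 jittered spheres clipped to the brain
#' mask: the simplest generator of contiguous, variably sized lesions.
#'
#' @param grid a [BrainGrid].
#' @param nPatients number of lesions.
#' @param sizeDistribution list with `rMin`, `rMax`: sphere radii (in
#'   voxels) are drawn uniformly from this range.
#' @param seed integer seed.
#' @return list of integer vectors of linear voxel indices (all
#'   nonempty, all inside the mask).
#' @export
sampleLesions <- function(grid, nPatients,
                          sizeDistribution = list(rMin = 1.2, rMax = 3.5),
                          seed) {
  stopifnot(!missing(seed))
  rMin <- sizeDistribution$rMin; rMax <- sizeDistribution$rMax
  stopifnot(rMin > 0, rMax >= rMin, rMax < min(grid@dims) / 2)
  dims <- grid@dims
  inmask <- which(grid@mask)
  co <- arrayInd(inmask, dims)
  withSeed(childSeed(seed, "lesions"), {
    lapply(seq_len(nPatients), function(i) {
      c0 <- co[sample.int(nrow(co), 1L), ]
      nSph <- sample.int(3L, 1L)
      vox <- integer(0)
      for (s in seq_len(nSph)) {
        r <- runif(1, rMin, rMax)
        ctr <- c0 + if (s == 1L) 0 else rnorm(3L, sd = r)
        d2 <- colSums((t(co) - ctr)^2)
        vox <- c(vox, inmask[d2 <= r^2])
      }
      sort(unique(c(vox, inmask[which.min(colSums((t(co) - c0)^2))])))
    })
  })
}

#' Generate behavior from lesions and ground truth
#'
#' Draws standard-normal latent factor scores per patient, decrements
#' each factor by `effect * fractionLesioned` of that factor's anatomy,
#' produces observed tests as `loadings %*% factors + noise`, and
#' deletes entries completely at random at `missingRate`.
#'
#' @param grid a [BrainGrid].
#' @param lesionList list of lesion voxel-index vectors (e.g. from
#'   [sampleLesions()]).
#' @param truth list with `loadings`, `uniquenesses`, `factorCov` (see
#'   [defaultGroundTruthParams()]).
#' @param anatomyEffects named list per factor with `voxels` and
#'   `effect` (see [planAnatomy()]); may be empty.
#' @param missingRate fraction of entries deleted, in [0, 1).
#' @param seed integer seed.
#' @return list with `cohort` ([LesionCohort]) and `truth`
#'   ([GroundTruth]).
#' @export
generateBehavior <- function(grid, lesionList,
                             truth = defaultGroundTruthParams(),
                             anatomyEffects = list(),
                             missingRate = 0.208, seed) {
  stopifnot(missingRate >= 0, missingRate < 1, !missing(seed))
  L <- truth$loadings
  p <- nrow(L); K <- ncol(L)
  if (is.null(colnames(L)) || is.null(rownames(L)))
    stop("truth$loadings must carry test and factor names")
  if (length(truth$uniquenesses) != p)
    stop("uniquenesses/test count mismatch with the loading pattern")
  bad <- setdiff(names(anatomyEffects), colnames(L))
  if (length(bad))
    stop("anatomyEffects refer to unknown factors: ",
         paste(bad, collapse = ", "))
  inmask <- which(grid@mask)
  for (f in names(anatomyEffects))
    if (!all(anatomyEffects[[f]]$voxels %in% inmask))
      stop("anatomy voxels must lie inside the brain mask")

  n <- length(lesionList)
  withSeed(childSeed(seed, "behavior"), {
    ch <- chol(truth$factorCov)
    eta <- matrix(rnorm(n * K), n, K) %*% ch
    colnames(eta) <- colnames(L)
    for (f in names(anatomyEffects)) {
      av <- anatomyEffects[[f]]$voxels
      if (!length(av)) next
      frac <- vapply(lesionList,
                     function(v) length(intersect(v, av)) / length(av), 1.0)
      eta[, f] <- eta[, f] - anatomyEffects[[f]]$effect * frac
    }
    eps <- matrix(rnorm(n * p), n, p) %*%
      diag(sqrt(truth$uniquenesses), p)
    Y <- eta %*% t(L) + eps
    colnames(Y) <- rownames(L)
    if (missingRate > 0) {
      drop <- matrix(runif(n * p) < missingRate, n, p)
      # never delete a patient's entire row
      full <- rowSums(!drop) == 0L
      drop[full, 1L] <- FALSE
      Y[drop] <- NA_real_
    }
  })
  ids <- sprintf("p%04d", seq_len(n))
  rownames(Y) <- ids
  cohort <- new("LesionCohort", grid = grid, lesions = lesionList,
                behavior = Y, missingRate = missingRate,
                patientIds = ids)
  gt <- new("GroundTruth", loadings = L,
            uniquenesses = truth$uniquenesses, factorCov = truth$factorCov,
            anatomyEffects = anatomyEffects, scores = eta)
  list(cohort = cohort, truth = gt)
}
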