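# Generators of the synthetic world: determinism, structural
# invariants, and generative fidelity.

test_that("parcellation tiles the mask and generation is deterministic", {
  b1 <- makeBrain(c(20, 24, 20), 3, nParcels = 20, nNetworks = 5,
                  seed = 7)
  lab <- b1$parcellation@labels
  mask <- b1$brain <- b1$grid@mask
  expect_setequal(unique(as.integer(lab[lab > 0])), 1:20)
  expect_true(all((lab > 0) == mask))            # parcels tile the mask
  expect_equal(sort(unique(b1$parcellation@parcelNetworks)), 1:5)

  b2 <- makeBrain(c(20, 24, 20), 3, nParcels = 20, nNetworks = 5,
                  seed = 7)
  expect_identical(b1$parcellation@labels, b2$parcellation@labels)
  expect_identical(b1$networks, b2$networks)

  expect_error(makeBrain(c(8, 8, 8), 3, nParcels = 500, nNetworks = 2,
                         seed = 1), "too small")
})

test_that("tractogram honors counts, endpoints and determinism", {
  w <- tinyWorld()
  b5 <- makeBrain(c(14, 16, 14), 3, nParcels = 5, nNetworks = 2, seed = 3)
  tr <- makeTractogram(b5$grid, b5$parcellation, nPerEdge = 10,
                       edgeDensity = 1, seed = 3)
  expect_length(tr@streamlines, 10 * choose(5, 2))

  lab <- b5$parcellation@labels
  firstLast <- t(vapply(tr@streamlines,
                        function(s) lab[c(s[1], s[length(s)])],
                        numeric(2)))
  expect_true(all(sort(unique(c(firstLast))) %in% 1:5))
  for (i in seq_len(nrow(tr@endpoints)))
    expect_setequal(firstLast[i, ], tr@endpoints[i, ])
  # every streamline voxel inside the brain mask
  expect_true(all(b5$grid@mask[unlist(tr@streamlines)]))

  tr2 <- makeTractogram(b5$grid, b5$parcellation, nPerEdge = 10,
                        edgeDensity = 1, seed = 3)
  expect_identical(tr@streamlines, tr2@streamlines)
})

test_that("normative functional series show the designed correlation", {
  b <- makeBrain(c(14, 16, 14), 3, nParcels = 8, nNetworks = 3, seed = 5)
  f <- makeNormativeFunctional(b$grid, b$networks, nSubjects = 100,
                               nTimepoints = 200,
                               withinNetworkCorr = 0.5, seed = 5)
  # Monte-Carlo check of the generative model on a voxel subset
  set.seed(1)
  sub <- sort(sample(length(f@maskIdx), 120))
  lab <- f@networkLabels[sub]
  same <- outer(lab, lab, `==`) & upper.tri(diag(length(sub)))
  diff <- !outer(lab, lab, `==`) & upper.tri(diag(length(sub)))
  within <- mean(vapply(f@series, function(S)
    mean(cor(S[, sub])[same]), 1.0))
  across <- mean(vapply(f@series, function(S)
    mean(cor(S[, sub])[diff]), 1.0))
  expect_gt(within, 0.45)
  expect_lt(within, 0.55)
  expect_lt(abs(across), 0.05)

  # near-independence limit
  f0 <- makeNormativeFunctional(b$grid, b$networks, nSubjects = 3,
                                nTimepoints = 400,
                                withinNetworkCorr = 1e-4, seed = 6)
  w0 <- mean(vapply(f0@series, function(S)
    mean(cor(S[, sub])[same]), 1.0))
  expect_lt(abs(w0), 0.05)

  f2 <- makeNormativeFunctional(b$grid, b$networks, nSubjects = 2,
                                nTimepoints = 60,
                                withinNetworkCorr = 0.5, seed = 9)
  f3 <- makeNormativeFunctional(b$grid, b$networks, nSubjects = 2,
                                nTimepoints = 60,
                                withinNetworkCorr = 0.5, seed = 9)
  expect_identical(f2@series, f3@series)
})

test_that("lesion sampler produces nonempty in-mask blobs, reproducibly", {
  w <- tinyWorld()
  les <- sampleLesions(w$brain$grid, 100, seed = 11)
  expect_length(les, 100)
  inmask <- which(w$brain$grid@mask)
  expect_true(all(vapply(les, length, 1L) >= 1L))
  expect_true(all(unlist(les) %in% inmask))

  # single-voxel-scale request
  tiny <- sampleLesions(w$brain$grid, 20,
                        sizeDistribution = list(rMin = 0.5, rMax = 1),
                        seed = 2)
  expect_true(all(vapply(tiny, length, 1L) >= 1L))
  expect_lt(max(vapply(tiny, length, 1L)), 10)

  les2 <- sampleLesions(w$brain$grid, 100, seed = 11)
  cov1 <- tabulate(unlist(les), prod(w$brain$grid@dims))
  cov2 <- tabulate(unlist(les2), prod(w$brain$grid@dims))
  expect_identical(cov1, cov2)
})

test_that("behavior generator hits the missingness band and is MCAR", {
  w <- tinyWorld()
  les <- sampleLesions(w$brain$grid, 473, seed = 21)
  gb <- generateBehavior(w$brain$grid, les, missingRate = 0.208,
                         seed = 21)
  Y <- behavior(gb$cohort)
  expect_equal(dim(Y), c(473, 23))
  mr <- mean(is.na(Y))
  expect_gt(mr, 0.188); expect_lt(mr, 0.228)

  # no deletion
  gb0 <- generateBehavior(w$brain$grid, les[1:50], missingRate = 0,
                          seed = 21)
  expect_false(anyNA(behavior(gb0$cohort)))

  # MCAR: missingness of one test uncorrelated with other tests' values
  les1 <- sampleLesions(w$brain$grid, 2000, seed = 22)
  gbm <- generateBehavior(w$brain$grid, les1, missingRate = 0.2,
                          seed = 22)
  Ym <- behavior(gbm$cohort)
  for (j in c(1, 12)) {
    miss <- as.numeric(is.na(Ym[, j]))
    for (k in c(5, 20)) {
      ok <- !is.na(Ym[, k])
      expect_lt(abs(cor(miss[ok], Ym[ok, k])), 0.05)
    }
  }
})

test_that("zero anatomy effects decouple factor scores from lesions", {
  w <- tinyWorld()
  les <- sampleLesions(w$brain$grid, 473, seed = 31)
  eff <- stats::setNames(rep(0, 2), c("g", "memory"))
  anat <- planAnatomy(w$brain, eff, seed = 31)
  gb <- generateBehavior(w$brain$grid, les, anatomyEffects = anat,
                         missingRate = 0, seed = 31)
  for (f in names(anat)) {
    av <- anat[[f]]$voxels
    frac <- vapply(les, function(v) length(intersect(v, av)), 1.0)
    expect_lt(abs(cor(gb$truth@scores[, f], frac)), 0.1)
  }
})

test_that("synthetic covariance converges to the implied structure", {
  # complete-data sample covariance vs Lambda Phi Lambda' + Theta
  sim <- simBehavior(20000, seed = 41)
  gt <- sim$truth
  implied <- gt$loadings %*% gt$factorCov %*% t(gt$loadings) +
    diag(gt$uniquenesses)
  expect_lt(max(abs(cov(sim$Y) - implied)), 0.05)
})

test_that("generateBehavior validates its configuration", {
  w <- tinyWorld()
  les <- sampleLesions(w$brain$grid, 10, seed = 1)
  badTruth <- defaultGroundTruthParams()
  badTruth$uniquenesses <- badTruth$uniquenesses[-1]
  expect_error(generateBehavior(w$brain$grid, les, truth = badTruth,
                                seed = 1), "mismatch")
  expect_error(
    generateBehavior(w$brain$grid, les,
                     anatomyEffects = list(nope = list(voxels = 1,
                                                       effect = 1)),
                     seed = 1), "unknown factors")
})
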