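# Structural and functional lesion network mapping.

test_that("disconnection matrix handles empty, total, oracle cases", {
  w <- tinyWorld()
  tr <- w$tract
  parc <- w$brain$parcellation

  M0 <- disconnectionMatrix(integer(0), tr, parc)
  expect_true(all(M0 == 0))

  # lesion covering all voxels of every streamline between one pair
  ab <- tr@endpoints[1, ]
  hit <- tr@endpoints[, 1] == ab[1] & tr@endpoints[, 2] == ab[2]
  lesion <- unique(unlist(tr@streamlines[hit]))
  M1 <- disconnectionMatrix(lesion, tr, parc)
  expect_equal(M1[ab[1], ab[2]], 100)
  expect_equal(M1, t(M1))
  expect_true(all(diag(M1) == 0))
  expect_true(all(M1 >= 0 & M1 <= 100))

  # brute-force per-streamline set-intersection oracle, random lesions
  set.seed(1)
  les <- sampleLesions(w$brain$grid, 5, seed = 5)
  for (lesion in les) {
    M <- disconnectionMatrix(lesion, tr, parc)
    P <- parc@nParcels
    oracle <- matrix(0, P, P)
    tot <- matrix(0, P, P)
    for (i in seq_along(tr@streamlines)) {
      a <- tr@endpoints[i, 1]; b <- tr@endpoints[i, 2]
      tot[a, b] <- tot[a, b] + 1
      if (length(intersect(tr@streamlines[[i]], lesion)))
        oracle[a, b] <- oracle[a, b] + 1
    }
    pct <- ifelse(tot > 0, 100 * oracle / pmax(tot, 1), 0)
    pct <- pct + t(pct)
    expect_identical(M, pct)
  }
})

test_that("growing a lesion never decreases disconnection", {
  w <- tinyWorld()
  set.seed(2)
  les <- sampleLesions(w$brain$grid, 3, seed = 7)
  for (lesion in les) {
    small <- lesion[seq_len(ceiling(length(lesion) / 2))]
    Ms <- disconnectionMatrix(small, w$tract, w$brain$parcellation)
    Ml <- disconnectionMatrix(lesion, w$tract, w$brain$parcellation)
    expect_true(all(Ml - Ms >= -1e-12))
  }
})

test_that("fLNM: single-voxel seed reduces to plain connectivity", {
  w <- tinyWorld()
  f <- w$func
  v <- f@maskIdx[25]
  m <- flnmMap(v, f)
  seedCol <- which(f@maskIdx == v)
  Zs <- vapply(f@series, function(S) {
    r <- apply(S, 2, function(v) cor(S[, seedCol], v))
    atanh(pmin(pmax(r, -0.999999), 0.999999))
  }, numeric(length(f@maskIdx)))
  tv <- rowMeans(Zs) / (apply(Zs, 1, sd) / sqrt(ncol(Zs)))
  tv[seedCol] <- NA
  expect_equal(m@values, tv, tolerance = 1e-10)
})

test_that("fLNM highlights the seeded network and is scale invariant", {
  w <- tinyWorld()
  f <- w$func
  # lesion entirely inside one network
  k <- f@networkLabels[1]
  lesionCols <- which(f@networkLabels == k)[1:6]
  lesion <- f@maskIdx[lesionCols]
  m <- flnmMap(lesion, f)
  inNet <- f@networkLabels == k
  inNet[lesionCols] <- NA
  expect_gt(mean(m@values[which(inNet)], na.rm = TRUE),
            mean(m@values[which(!inNet)], na.rm = TRUE))

  # rescaling all series leaves the T map unchanged
  f2 <- f
  f2@series <- lapply(f@series, function(S) 3.7 * S)
  m2 <- flnmMap(lesion, f2)
  expect_equal(m@values, m2@values, tolerance = 1e-9)

  # subject order invariance: shuffling the normative subjects leaves
  # the map unchanged
  f3 <- f
  f3@series <- f@series[rev(seq_along(f@series))]
  m3 <- flnmMap(lesion, f3)
  expect_equal(m3@values, m@values, tolerance = 1e-12)
})

test_that("edgewise mapping tests each edge once and finds planted effects", {
  w <- tinyWorld()
  grid <- w$brain$grid
  set.seed(3)
  les <- sampleLesions(grid, 200, seed = 31)
  mats <- lapply(les, disconnectionMatrix, tractogram = w$tract,
                 parcellation = w$brain$parcellation)
  ef <- edgeFeatures(mats)
  P <- w$brain$parcellation@nParcels
  expect_equal(ncol(ef$X), choose(P, 2))
  expect_equal(nrow(ef$edges), choose(P, 2))

  # plant an effect on the most-disconnected edge
  nz <- colSums(ef$X > 0)
  j <- which.max(nz)
  y <- rnorm(200) - 1.2 * ef$X[, j] / max(ef$X[, j])
  covar <- matrix(vapply(les, logLesionVolume, 1.0, grid = grid))
  sm <- edgewiseMap(mats, y, covar, nPerm = 200, seed = 32)
  expect_true(j %in% sigFeatures(sm))

  # permuting scores destroys the finding (null familywise behavior)
  set.seed(4)
  smNull <- edgewiseMap(mats, sample(rnorm(200)), covar, nPerm = 200,
                        seed = 33)
  expect_lte(sum(smNull@sigMask), 2)
})

test_that("zero-disconnection lesions still contribute to LBM", {
  w <- tinyWorld()
  grid <- w$brain$grid
  # find a voxel not crossed by any streamline
  crossed <- unique(w$tract@flatVox)
  free <- setdiff(which(grid@mask), crossed)
  expect_gt(length(free), 0)
  lesion <- free[1]
  M <- disconnectionMatrix(lesion, w$tract, w$brain$parcellation)
  expect_true(all(M == 0))
  X <- lesionMatrix(list(lesion), grid)
  expect_equal(sum(X), 1)
})

test_that("voxelwise fLNM group mapping recovers planted coupling", {
  w <- tinyWorld()
  grid <- w$brain$grid
  f <- w$func
  set.seed(5)
  n <- 120
  les <- sampleLesions(grid, n, seed = 51)
  maps <- lapply(les, flnmMap, normative = f)
  # plant: deficit proportional to lesion load in network 1
  net1 <- f@maskIdx[f@networkLabels == 1]
  load1 <- vapply(les, function(v) length(intersect(v, net1)), 1.0)
  y <- rnorm(n) - 1.5 * load1 / max(load1)
  covar <- matrix(vapply(les, logLesionVolume, 1.0, grid = grid))
  sm <- voxelwiseFlnmMapping(maps, y, covar, nPerm = 200, seed = 52)
  sig <- sigFeatures(sm)
  expect_gt(length(sig), 0)
  expect_gt(mean(sig %in% net1), 0.5)

  # permuted scores: nothing survives
  smn <- voxelwiseFlnmMapping(maps, sample(y), covar, nPerm = 200,
                              seed = 53)
  expect_lte(sum(smn@sigMask), 2)
})
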