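# Mass-univariate lesion-behavior mapping and PLSR.

test_that("log lesion volume follows its definition", {
  w <- tinyWorld()
  grid <- w$brain$grid
  v1 <- which(grid@mask)[1]
  expect_equal(logLesionVolume(v1, grid), log(27))
  v2 <- which(grid@mask)[1:10]
  expect_equal(logLesionVolume(v2, grid) - logLesionVolume(v2[1:5], grid),
               log(2))
  expect_error(logLesionVolume(integer(0), grid), "empty")
})

test_that("partial correlation equals the residualization oracle", {
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    X <- matrix(rbinom(n * 6, 1, 0.4), n, 6)
    X <- X[, colSums(X) >= 2 & colSums(X) <= n - 2, drop = FALSE]
    y <- rnorm(n)
    Z <- cbind(rnorm(n), rnorm(n))
    sm <- voxelwisePartialCorr(X, y, Z, minLesion = 2)
    # oracle: residualize via lm, then correlate
    oracle <- apply(X[, match(sm@featureIds, seq_len(ncol(X))),
                      drop = FALSE], 2, function(x)
      cor(resid(lm(x ~ Z)), resid(lm(y ~ Z))))
    expect_lt(max(abs(sm@r - oracle)), 1e-12)
    # t relation holds
    expect_equal(sm@t, sm@r * sqrt((n - 2 - 2) / (1 - sm@r^2)),
                 tolerance = 1e-12)
  }
})

test_that("partialling nothing gives plain Pearson; shared variance dies", {
  set.seed(2)
  n <- 80
  X <- matrix(rbinom(n * 20, 1, 0.3), n, 20)
  y <- rnorm(n)
  sm0 <- voxelwisePartialCorr(X, y, NULL, minLesion = 4)
  plain <- apply(X[, match(sm0@featureIds, seq_len(ncol(X))),
                   drop = FALSE], 2, cor, y = y)
  expect_equal(unname(sm0@r), unname(plain), tolerance = 1e-12)

  # score identical to the covariate: no unique variance anywhere
  smz <- voxelwisePartialCorr(X, y, matrix(y), minLesion = 4)
  expect_lt(max(abs(smz@r)), 1e-8)
})

test_that("constant and rare features are excluded, recorded", {
  set.seed(3)
  n <- 60
  X <- matrix(c(rep(0, n), rep(1, n), rbinom(2 * n, 1, 0.5)), n, 4)
  sm <- voxelwisePartialCorr(X, rnorm(n), NULL, minLesion = 4)
  expect_false(1L %in% sm@featureIds)
  expect_false(2L %in% sm@featureIds)
  expect_length(sm@allFeatureIds, 4L)
})

test_that("v = 1 threshold equals the max-statistic threshold", {
  set.seed(4)
  n <- 60
  X <- matrix(rbinom(n * 40, 1, 0.4), n, 40)
  y <- rnorm(n)
  Z <- matrix(rnorm(n))
  sm <- permutationFwe(X, y, Z, nPerm = 150, v = 1, alpha = 0.05,
                       seed = 9)
  # manual max-statistic null from the same seeded permutation stream
  obs <- voxelwisePartialCorr(X, y, Z)
  keep <- match(obs@featureIds, seq_len(ncol(X)))
  perms <- gLDM:::withSeed(gLDM:::childSeed(9, "fwe-perm"),
    vapply(1:150, function(b) y[sample.int(n)], numeric(n)))
  mx <- apply(perms, 2, function(yp) {
    r <- apply(X[, keep], 2, function(x)
      cor(resid(lm(x ~ Z)), resid(lm(yp ~ Z))))
    max(abs(r * sqrt((n - 3) / (1 - r^2))))
  })
  nullStats <- c(max(abs(obs@t)), mx)
  expect_equal(sm@threshold,
               sort(nullStats)[ceiling(0.95 * length(nullStats))],
               tolerance = 1e-10)
})

test_that("threshold is monotone in alpha and maximal at v = 1", {
  set.seed(5)
  n <- 80
  X <- matrix(rbinom(n * 60, 1, 0.4), n, 60)
  y <- rnorm(n)
  thr <- vapply(c(0.01, 0.05, 0.2), function(a)
    permutationFwe(X, y, NULL, nPerm = 150, v = 1, alpha = a,
                   seed = 3)@threshold, 1.0)
  expect_true(all(diff(thr) <= 1e-12))
  thrV <- vapply(c(1L, 3L, 10L), function(v)
    permutationFwe(X, y, NULL, nPerm = 150, v = v, alpha = 0.05,
                   seed = 3)@threshold, 1.0)
  expect_true(all(diff(thrV) <= 1e-12))
})

test_that("a planted deficit region is detected under FWE control", {
  w <- tinyWorld()
  grid <- w$brain$grid
  set.seed(6)
  les <- sampleLesions(grid, 473, seed = 61)
  X <- lesionMatrix(les, grid)
  eff <- stats::setNames(1.5, "g")
  anat <- planAnatomy(w$brain, eff, seed = 61)
  av <- anat$g$voxels
  frac <- vapply(les, function(v) length(intersect(v, av)) / length(av),
                 1.0)
  y <- rnorm(473) - 1.5 * frac / max(frac)
  covar <- matrix(vapply(les, logLesionVolume, 1.0, grid = grid))
  sm <- permutationFwe(X, y, covar, nPerm = 300, v = 1, alpha = 0.05,
                       seed = 62)
  sig <- sigFeatures(sm)
  expect_gt(length(intersect(sig, av)), 0)
  # lesions harming behavior show negative correlations
  expect_lt(min(sm@r[match(intersect(sig, av), sm@featureIds)]), 0)
})

test_that("PLSR finds planted weights and stays honest under the null", {
  w <- tinyWorld()
  grid <- w$brain$grid
  les <- sampleLesions(grid, 80, seed = 71)
  X <- lesionMatrix(les, grid)
  keep <- colSums(X) >= 4 & colSums(X) <= 76
  j <- which(keep)[which.max(colSums(X)[keep])]
  y <- -2 * X[, j]
  pl <- plsrMap(X, y, NULL, folds = 5, repeats = 1, maxComponents = 3,
                seed = 1)
  expect_equal(names(which.max(abs(pl$weights))), colnames(X)[j])

  # permuted scores: no predictive signal on average
  set.seed(7)
  nullCv <- vapply(1:15, function(i)
    mean(plsrMap(X, sample(y), NULL, folds = 5, repeats = 1,
                 maxComponents = 3, seed = 100 + i)$cvCor), 1.0)
  expect_lte(mean(nullCv), 0.05)

  # leave-one-out boundary configuration runs
  plo <- plsrMap(X[1:25, ], y[1:25], NULL, folds = 25, repeats = 1,
                 maxComponents = 2, seed = 3)
  expect_true(is.finite(plo$varianceExplained))
})
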