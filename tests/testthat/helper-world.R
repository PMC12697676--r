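# Shared fixtures, built in code once per test run.

tinyWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      brain <- makeBrain(c(14, 16, 14), 3, nParcels = 10, nNetworks = 3,
                         seed = 101)
      cache <<- list(
        brain = brain,
        tract = makeTractogram(brain$grid, brain$parcellation,
                               nPerEdge = 4, edgeDensity = 1, seed = 101),
        func = makeNormativeFunctional(brain$grid, brain$networks,
                                       nSubjects = 6, nTimepoints = 90,
                                       withinNetworkCorr = 0.5,
                                       seed = 101))
    }
    cache
  }
})

# Complete behavior data drawn from the default bifactor ground truth.
simBehavior <- function(n, seed, missingRate = 0) {
  gt <- defaultGroundTruthParams()
  K <- ncol(gt$loadings)
  set.seed(seed)
  eta <- matrix(rnorm(n * K), n, K)
  colnames(eta) <- colnames(gt$loadings)
  Y <- eta %*% t(gt$loadings) +
    matrix(rnorm(n * nrow(gt$loadings)), n) %*%
    diag(sqrt(gt$uniquenesses))
  colnames(Y) <- rownames(gt$loadings)
  if (missingRate > 0) Y[matrix(runif(length(Y)) < missingRate,
                                n, ncol(Y))] <- NA
  list(Y = Y, eta = eta, truth = gt)
}

# Random smooth-ish statistic maps over a common feature set, both
# model sets drawn from the same exchangeable generator.
nullMapSets <- function(K, nFeat, seed) {
  set.seed(seed)
  base <- rnorm(nFeat)
  gen <- function() lapply(seq_len(K), function(i)
    0.5 * base + rnorm(nFeat))
  a <- gen(); b <- gen()
  names(a) <- names(b) <- paste0("d", seq_len(K))
  list(a = a, b = b)
}
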