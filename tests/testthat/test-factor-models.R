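# Confirmatory factor modeling: FIML correctness, fit statistics,
# reliability, nested tests, factor scores.

test_that("FIML reduces to complete-data ML without missingness", {
  sim <- simBehavior(400, seed = 1)
  spec <- bifactorSpec()
  f1 <- fitCfa(sim$Y, spec, "fiml", nStarts = 1)
  f2 <- fitCfa(sim$Y, spec, "ml_complete", nStarts = 1)
  expect_lt(max(abs(factorLoadings(f1) - factorLoadings(f2))), 1e-4)
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-8)
})

test_that("loadings are recovered from data simulated at known truth", {
  sim <- simBehavior(1000, seed = 2)
  spec <- bifactorSpec()
  fit <- fitCfa(sim$Y, spec, nStarts = 1)
  expect_true(fit@converged)
  free <- spec@pattern == 1
  rmse <- sqrt(mean((factorLoadings(fit) - sim$truth$loadings)[free]^2))
  expect_lt(rmse, 0.05)
  # uniquenesses too
  expect_lt(max(abs(uniquenesses(fit) - sim$truth$uniquenesses)), 0.15)
})

test_that("a saturated specification reaches chi-square zero", {
  # one factor on 3 variables: 3 loadings + 3 uniquenesses = 6 = p(p+1)/2
  set.seed(3)
  Y <- matrix(rnorm(600), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  Y[, 2] <- Y[, 1] * 0.5 + Y[, 2]
  spec <- new("FactorModelSpec", tests = c("a", "b", "c"), factors = "f",
              pattern = matrix(1, 3, 1,
                               dimnames = list(c("a", "b", "c"), "f")),
              factorCovStructure = "orthogonal",
              residualCovPairs = matrix(character(0), 0, 2))
  fit <- fitCfa(Y, spec, nStarts = 2)
  expect_equal(dof(fit), 0)
  expect_lt(chiSquare(fit), 0.02)
  expect_error(fitIndices(fit, behavior = Y), "df = 0")
})

test_that("fit indices match a hand formula evaluation", {
  # fixed 4-variable covariance realized exactly in the sample
  S <- matrix(c(1, .5, .4, .3,
                .5, 1, .35, .3,
                .4, .35, 1, .45,
                .3, .3, .45, 1), 4, 4)
  set.seed(4)
  n <- 120
  Z <- matrix(rnorm(n * 4), n, 4)
  Z <- scale(qr.Q(qr(scale(Z, scale = FALSE))) * sqrt(n - 1))
  Y <- Z %*% chol(S)
  colnames(Y) <- c("x1", "x2", "x3", "x4")
  spec <- new("FactorModelSpec", tests = colnames(Y), factors = "f",
              pattern = matrix(1, 4, 1,
                               dimnames = list(colnames(Y), "f")),
              factorCovStructure = "orthogonal",
              residualCovPairs = matrix(character(0), 0, 2))
  fit <- fitCfa(Y, spec, nStarts = 2)
  idx <- fitIndices(fit, behavior = Y)

  # independent evaluation from the chi-square statistics
  base <- independenceModel(Y, -2 * fit@loglikSaturated)
  cm <- chiSquare(fit); dm <- dof(fit)
  cb <- base$chiSquare; db <- base$df
  expect_equal(unname(idx["cfi"]),
               1 - max(cm - dm, 0) / max(cb - db, cm - dm, 0),
               tolerance = 1e-8)
  expect_equal(unname(idx["tli"]),
               ((cb / db) - (cm / dm)) / ((cb / db) - 1),
               tolerance = 1e-8)
  expect_equal(unname(idx["rmsea"]),
               sqrt(max(cm - dm, 0) / (dm * (fit@nUsed - 1))),
               tolerance = 1e-8)
  # SRMR against a direct standardized-residual computation
  Simp <- factorLoadings(fit) %*% factorCov(fit) %*%
    t(factorLoadings(fit)) + fit@residualCov
  Ssat <- fit@satSigma
  resid <- (Ssat - Simp) / sqrt(tcrossprod(diag(Ssat)))
  expect_equal(unname(idx["srmr"]),
               sqrt(mean(resid[lower.tri(resid, diag = TRUE)]^2)),
               tolerance = 1e-8)
})

test_that("chi-square difference test is calibrated and powerful", {
  # restricted truth: single factor on 5 tests; full model frees one
  # residual covariance pair
  tests <- paste0("x", 1:5)
  mkspec <- function(pairs) new("FactorModelSpec", tests = tests,
    factors = "f",
    pattern = matrix(1, 5, 1, dimnames = list(tests, "f")),
    factorCovStructure = "orthogonal",
    residualCovPairs = pairs)
  s0 <- mkspec(matrix(character(0), 0, 2))
  s1 <- mkspec(rbind(c("x1", "x2")))

  gen <- function(n, rho) {
    lam <- rep(0.7, 5)
    S <- tcrossprod(lam) + diag(1 - lam^2)
    S[1, 2] <- S[2, 1] <- S[1, 2] + rho
    Y <- matrix(rnorm(n * 5), n) %*% chol(S)
    colnames(Y) <- tests
    Y
  }

  set.seed(5)
  nrep <- 120
  rejNull <- rejAlt <- logical(nrep)
  for (i in seq_len(nrep)) {
    Y0 <- gen(300, 0)
    d0 <- chisqDiffTest(fitCfa(Y0, s0, nStarts = 1),
                        fitCfa(Y0, s1, nStarts = 1))
    rejNull[i] <- d0$p < 0.05
    if (i <= 40) {
      Y1 <- gen(300, 0.25)
      d1 <- chisqDiffTest(fitCfa(Y1, s0, nStarts = 1),
                          fitCfa(Y1, s1, nStarts = 1))
      rejAlt[i] <- d1$p < 0.05
    }
  }
  expect_lt(mean(rejNull), 0.11)   # ~0.05 within binomial error
  expect_gt(mean(rejNull), 0.005)
  expect_gt(mean(rejAlt[1:40]), 0.9)

  # degenerate nesting
  f0 <- fitCfa(gen(200, 0), s0, nStarts = 1)
  expect_error(chisqDiffTest(f0, f0), "not nested")
})

test_that("omega hierarchical matches its closed form", {
  # 4 items, g loadings 0.6, uniqueness 0.64: omega = 5.76 / 8.32
  tests <- paste0("y", 1:4)
  spec <- new("FactorModelSpec", tests = tests, factors = "g",
              pattern = matrix(1, 4, 1, dimnames = list(tests, "g")),
              factorCovStructure = "orthogonal",
              residualCovPairs = matrix(character(0), 0, 2))
  fit <- new("FittedFactorModel", spec = spec,
             loadings = matrix(0.6, 4, 1,
                               dimnames = list(tests, "g")),
             uniquenesses = stats::setNames(rep(0.64, 4), tests),
             residualCov = diag(rep(0.64, 4)), factorCov = diag(1),
             mu = stats::setNames(rep(0, 4), tests), loglik = 0,
             loglikSaturated = 0, chiSquare = 0, df = 2, nUsed = 100L,
             converged = TRUE, satSigma = diag(4), satMu = rep(0, 4),
             se = list(), estimator = "fiml")
  expect_equal(unname(omegaHierarchical(fit)), 5.76 / 8.32,
               tolerance = 1e-10)

  # zero loadings give omega 0; a full-battery fit stays in [0,1]
  fit0 <- fit
  fit0@loadings[] <- 0
  expect_equal(unname(omegaHierarchical(fit0)), 0)

  sim <- simBehavior(600, seed = 6)
  bfit <- fitCfa(sim$Y, bifactorSpec(), nStarts = 1)
  om <- omegaHierarchical(bfit)
  expect_length(om, 6)
  expect_true(all(om >= 0 & om <= 1))
})

test_that("factor scores recover truth and handle missingness", {
  sim <- simBehavior(1000, seed = 7)
  fit <- fitCfa(sim$Y, bifactorSpec(), nStarts = 1)
  sc <- factorScores(fit, sim$Y)
  expect_gt(cor(sc[, "g"], sim$eta[, "g"]), 0.85)

  # behavior at the estimated means scores ~0
  atMean <- matrix(fit@mu, 1, dimnames = list(NULL, names(fit@mu)))
  expect_lt(max(abs(factorScores(fit, atMean))), 1e-8)

  # a patient missing 33% of tests still gets finite scores
  Ym <- sim$Y
  Ym[1, sample(23, 8)] <- NA
  scm <- factorScores(fit, Ym)
  expect_true(all(is.finite(scm[1, ])))

  Ybad <- sim$Y
  Ybad[2, ] <- NA
  expect_error(factorScores(fit, Ybad), "zero observed")
})

test_that("bifactor scores on orthogonal truth stay near-orthogonal", {
  sim <- simBehavior(1000, seed = 8)
  fit <- fitCfa(sim$Y, bifactorSpec(), nStarts = 1)
  sc <- factorScores(fit, sim$Y)
  cc <- cor(sc)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.2)
})

test_that("model chi-squares respect nesting against the saturated fit", {
  sim <- simBehavior(300, seed = 9, missingRate = 0.2)
  bf <- fitCfa(sim$Y, bifactorSpec(), nStarts = 1)
  cf <- fitCfa(sim$Y, correlatedFactorsSpec(), nStarts = 1)
  expect_gte(chiSquare(bf), 0)
  expect_gte(chiSquare(cf), 0)
  expect_lte(bf@loglik, bf@loglikSaturated + 1e-6)
  expect_lte(cf@loglik, cf@loglikSaturated + 1e-6)
  # correlated-factors correlations reflect the shared g variance
  phi <- factorCov(cf)[upper.tri(factorCov(cf))]
  expect_true(all(phi > 0.3))
})
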