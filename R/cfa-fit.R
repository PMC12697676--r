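## Confirmatory factor analysis by (full-information) maximum likelihood.
##
## The covariance structure is Sigma = Lambda Phi Lambda' + Theta with
## factor variances fixed to 1 (all loadings free), which identifies the
## model and makes omega coefficients direct. Missing data are handled
## casewise: the likelihood is accumulated over missing-data patterns
## with sufficient statistics, evaluated in compiled code, and the
## analytic gradient is chained from dF/dSigma. Free factor
## correlations are parameterized as tanh of unconstrained reals;
## uniquenesses as exp of unconstrained reals (so Heywood cases appear
## as boundary solutions, never negative variances).

## ---- missing-data pattern bookkeeping -------------------------------

buildPatterns <- function(Y) {
  p <- ncol(Y)
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0L
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  if (any(colSums(obs) == 0L))
    stop("every test needs >= 1 observed value")
  key <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  groups <- split(seq_len(nrow(Y)), key)
  pats <- lapply(groups, function(rows) {
    o <- which(obs[rows[1L], ])
    Yo <- Y[rows, o, drop = FALSE]
    list(idx = o - 1L, midx = setdiff(seq_len(p), o) - 1L,
         n = length(rows), rows = rows,
         sumY = colSums(Yo), Syy = crossprod(Yo))
  })
  list(patterns = pats, n = nrow(Y), p = p, keep = which(keep))
}

## ---- saturated (unstructured) model via EM --------------------------

emSaturated <- function(pat, tol = 1e-7, maxit = 2000) {
  p <- pat$p
  n <- pat$n
  # moment start from available data
  sumY <- Reduce(`+`, lapply(pat$patterns, function(g) {
    v <- numeric(p); v[g$idx + 1L] <- g$sumY; v
  }))
  cnt <- Reduce(`+`, lapply(pat$patterns, function(g) {
    v <- numeric(p); v[g$idx + 1L] <- g$n; v
  }))
  mu <- sumY / cnt
  # diagonal start from marginal second moments
  diagS <- numeric(p)
  for (g in pat$patterns) {
    o <- g$idx + 1L
    diagS[o] <- diagS[o] + diag(g$Syy) - 2 * g$sumY * mu[o] +
      g$n * mu[o]^2
  }
  Sigma <- diag(pmax(diagS / cnt, 1e-6), p)

  fOld <- Inf
  for (it in seq_len(maxit)) {
    st <- .emStepCpp(mu, Sigma, pat$patterns)
    mu <- as.vector(st$T1) / n
    Sigma <- st$T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    if (inherits(try(chol(Sigma), silent = TRUE), "try-error"))
      Sigma <- Sigma + diag(1e-8 * mean(diag(Sigma)), p)
    f <- .fimlEvalCpp(mu, Sigma, pat$patterns, FALSE)$f
    if (is.finite(f) && abs(fOld - f) < tol * (abs(f) + 1)) break
    fOld <- f
  }
  list(mu = mu, Sigma = Sigma, minus2ll = f)
}

## ---- parameter mapping ----------------------------------------------

parLayout <- function(spec) {
  p <- length(spec@tests)
  K <- length(spec@factors)
  freeIdx <- which(spec@pattern == 1)
  nL <- length(freeIdx)
  nPairs <- nrow(spec@residualCovPairs)
  nPhi <- if (spec@factorCovStructure == "free") K * (K - 1L) / 2L else 0L
  pairIdx <- if (nPairs) cbind(match(spec@residualCovPairs[, 1], spec@tests),
                               match(spec@residualCovPairs[, 2], spec@tests))
             else matrix(0L, 0, 2)
  if (nPairs && any(is.na(pairIdx)))
    stop("residualCovPairs refer to unknown tests")
  list(p = p, K = K, freeIdx = freeIdx, nL = nL, nPairs = nPairs,
       nPhi = nPhi, pairIdx = pairIdx,
       nFree = nL + p + nPairs + nPhi,  # excluding saturated means
       total = p + nL + p + nPairs + nPhi,
       sl = list(mu = 1:p, lambda = p + seq_len(nL),
                 ltheta = p + nL + 1:p,
                 pair = if (nPairs) p + nL + p + seq_len(nPairs) else integer(0),
                 phi = if (nPhi) p + nL + p + nPairs + seq_len(nPhi)
                       else integer(0)))
}

parToModel <- function(par, spec, lay) {
  L <- matrix(0, lay$p, lay$K,
              dimnames = list(spec@tests, spec@factors))
  L[lay$freeIdx] <- par[lay$sl$lambda]
  theta <- exp(par[lay$sl$ltheta])
  Theta <- diag(theta, lay$p)
  if (lay$nPairs)
    for (i in seq_len(lay$nPairs)) {
      a <- lay$pairIdx[i, 1]; b <- lay$pairIdx[i, 2]
      Theta[a, b] <- Theta[b, a] <- par[lay$sl$pair][i]
    }
  Phi <- diag(lay$K)
  if (lay$nPhi) {
    z <- tanh(par[lay$sl$phi])
    Phi[upper.tri(Phi)] <- z
    Phi <- Phi + t(Phi) - diag(diag(Phi))
    diag(Phi) <- 1
  }
  list(mu = par[lay$sl$mu], L = L, theta = theta, Theta = Theta, Phi = Phi,
       Sigma = L %*% Phi %*% t(L) + Theta)
}

## ---- fit ------------------------------------------------------------

#' Fit a confirmatory factor model
#'
#' Maximizes the multivariate-normal likelihood of a
#' [FactorModelSpec] by quasi-Newton optimization with analytic
#' gradients. With `estimator = "fiml"` the likelihood is accumulated
#' casewise over each patient's observed subset (full-information
#' maximum likelihood); `"ml_complete"` first drops incomplete rows.
#' The chi-square statistic is the likelihood ratio against the
#' saturated model, whose FIML solution is found by EM.
#'
#' @param behavior patients x tests numeric matrix (`NA` = missing).
#' @param spec a [FactorModelSpec].
#' @param estimator `"fiml"` (default) or `"ml_complete"`.
#' @param nStarts optimizer starts (first deterministic, the rest
#'   jittered); the best solution is kept.
#' @param seed seed for the jittered restarts.
#' @param computeSe also compute standard errors from a
#'   finite-difference Hessian of the analytic gradient.
#' @param maxit BFGS iteration cap per start.
#' @return a [FittedFactorModel].
#' @export
fitCfa <- function(behavior, spec, estimator = c("fiml", "ml_complete"),
                   nStarts = 3, seed = 1, computeSe = FALSE,
                   maxit = 1000) {
  estimator <- match.arg(estimator)
  stopifnot(is.matrix(behavior))
  if (!is.null(colnames(behavior))) {
    if (!all(spec@tests %in% colnames(behavior)))
      stop("behavior lacks tests required by the spec")
    behavior <- behavior[, spec@tests, drop = FALSE]
  } else if (ncol(behavior) != length(spec@tests)) {
    stop("behavior column count does not match the spec's tests")
  }
  if (estimator == "ml_complete")
    behavior <- behavior[stats::complete.cases(behavior), , drop = FALSE]

  lay <- parLayout(spec)
  if (lay$nFree > lay$p * (lay$p + 1) / 2)
    stop("model has more free parameters than covariance moments")
  pat <- buildPatterns(behavior)
  if (pat$n < lay$nFree)
    stop("fewer cases than free parameters")

  cache <- new.env(parent = emptyenv())
  evalAt <- function(par, grad) {
    if (!is.null(cache$par) && identical(cache$par, par) &&
        (!grad || !is.null(cache$res$G)))
      return(cache$res)
    m <- parToModel(par, spec, lay)
    res <- .fimlEvalCpp(m$mu, m$Sigma, pat$patterns, grad)
    res$model <- m
    cache$par <- par
    cache$res <- res
    res
  }
  fn <- function(par) {
    r <- evalAt(par, FALSE)
    if (!r$ok || !is.finite(r$f)) 1e12 else r$f
  }
  gr <- function(par) {
    r <- evalAt(par, TRUE)
    if (!r$ok) return(rep(0, length(par)))
    m <- r$model
    G <- r$G
    Gs <- (G + t(G)) / 2
    g <- numeric(length(par))
    g[lay$sl$mu] <- r$gmu
    dL <- 2 * Gs %*% m$L %*% m$Phi
    g[lay$sl$lambda] <- dL[lay$freeIdx]
    g[lay$sl$ltheta] <- diag(Gs) * m$theta
    if (lay$nPairs)
      g[lay$sl$pair] <- 2 * Gs[lay$pairIdx]
    if (lay$nPhi) {
      M <- t(m$L) %*% Gs %*% m$L
      z <- m$Phi[upper.tri(m$Phi)]
      g[lay$sl$phi] <- 2 * M[upper.tri(M)] * (1 - z^2)
    }
    g
  }

  # deterministic start from marginal moments
  mu0 <- vapply(seq_len(lay$p),
                function(j) mean(behavior[, j], na.rm = TRUE), 1.0)
  s0 <- vapply(seq_len(lay$p),
               function(j) stats::sd(behavior[, j], na.rm = TRUE), 1.0)
  s0[!is.finite(s0) | s0 <= 0] <- 1
  L0 <- matrix(0, lay$p, lay$K)
  nload <- rowSums(spec@pattern)
  L0[lay$freeIdx] <- (0.6 * s0 / sqrt(nload))[row(spec@pattern)[lay$freeIdx]]
  start0 <- c(mu0, L0[lay$freeIdx], log(0.5 * s0^2),
              rep(0, lay$nPairs), rep(0, lay$nPhi))

  best <- NULL
  withSeed(childSeed(seed, "cfa-starts"), {
    for (s in seq_len(max(1L, nStarts))) {
      start <- start0
      if (s > 1L) {
        start[lay$sl$lambda] <- start[lay$sl$lambda] +
          rnorm(lay$nL, sd = 0.15 * mean(s0))
        start[lay$sl$ltheta] <- start[lay$sl$ltheta] + rnorm(lay$p, sd = 0.3)
        if (lay$nPhi) start[lay$sl$phi] <- rnorm(lay$nPhi, sd = 0.2)
      }
      f0 <- fn(start)
      opt <- stats::optim(start, fn, gr, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-10))
      # likelihood-ascent guard: never accept a solution worse than its
      # own start
      if (opt$value > f0 + 1e-8) {
        opt$value <- f0
        opt$par <- start
        opt$convergence <- 1L
      }
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  })

  m <- parToModel(best$par, spec, lay)
  # sign convention: each factor's loading sum nonnegative
  flip <- colSums(m$L) < 0
  if (any(flip)) {
    m$L[, flip] <- -m$L[, flip]
    m$Phi[flip, ] <- -m$Phi[flip, ]
    m$Phi[, flip] <- -m$Phi[, flip]
    diag(m$Phi) <- 1
  }
  if (any(m$theta < 1e-3 * s0^2))
    warning("uniqueness at boundary (Heywood case); ",
            "estimate clamped by the log parameterization")

  sat <- emSaturated(pat)
  chi2 <- max(best$value - sat$minus2ll, 0)
  df <- lay$p * (lay$p + 1) / 2 - lay$nFree
  converged <- best$convergence == 0L

  se <- list()
  if (computeSe) {
    H <- fdHessian(gr, best$par)
    V <- try(2 * solve((H + t(H)) / 2), silent = TRUE)
    if (!inherits(V, "try-error")) {
      sdiag <- sqrt(pmax(diag(V), 0))
      seL <- matrix(NA_real_, lay$p, lay$K,
                    dimnames = dimnames(m$L))
      seL[lay$freeIdx] <- sdiag[lay$sl$lambda]
      se <- list(loadings = seL,
                 uniquenesses = sdiag[lay$sl$ltheta] * m$theta,
                 mu = sdiag[lay$sl$mu])
    }
  }

  new("FittedFactorModel", spec = spec, loadings = m$L,
      uniquenesses = stats::setNames(m$theta, spec@tests),
      residualCov = m$Theta, factorCov = m$Phi,
      mu = stats::setNames(m$mu, spec@tests),
      loglik = -best$value / 2, loglikSaturated = -sat$minus2ll / 2,
      chiSquare = chi2, df = df, nUsed = pat$n,
      converged = converged, satSigma = sat$Sigma, satMu = sat$mu,
      se = se, estimator = estimator)
}

## central-difference Hessian of a gradient function
fdHessian <- function(gr, par, eps = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- eps * max(1, abs(par[i]))
    H[i, ] <- (gr(par + e) - gr(par - e)) / (2 * e[i])
  }
  (H + t(H)) / 2
}

#' Fit the independence (baseline) model
#'
#' Diagonal covariance, free means; with missing data the per-variable
#' MLEs are closed form over each column's observed values. Used as the
#' baseline for incremental fit indices.
#'
#' @param behavior patients x tests matrix.
#' @param satMinus2ll saturated-model -2 loglik on the same cases (from
#'   a [fitCfa()] result: `-2 * model@loglikSaturated`).
#' @return list with `minus2ll`, `chiSquare`, `df`.
#' @export
independenceModel <- function(behavior, satMinus2ll) {
  keep <- rowSums(!is.na(behavior)) > 0L
  Y <- behavior[keep, , drop = FALSE]
  p <- ncol(Y)
  m2ll <- 0
  for (j in seq_len(p)) {
    y <- Y[, j]; y <- y[!is.na(y)]
    s2 <- mean((y - mean(y))^2)
    m2ll <- m2ll + length(y) * (log(2 * pi) + log(s2)) +
      sum((y - mean(y))^2) / s2
  }
  list(minus2ll = m2ll, chiSquare = max(m2ll - satMinus2ll, 0),
       df = p * (p + 1) / 2 - p)
}
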