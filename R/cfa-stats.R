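## Fit statistics, reliability, nested tests, factor scores.

#' Fit indices for a fitted factor model
#'
#' Standard maximum-likelihood fit indices:
#' \deqn{CFI = 1 - \max(\chi^2_m - df_m, 0) /
#'   \max(\chi^2_b - df_b, \chi^2_m - df_m, 0)}
#' \deqn{TLI = ((\chi^2_b/df_b) - (\chi^2_m/df_m)) / ((\chi^2_b/df_b) - 1)}
#' \deqn{RMSEA = \sqrt{\max(\chi^2_m - df_m, 0) / (df_m (n - 1))}}
#' SRMR is the root mean squared standardized residual covariance
#' between the saturated (EM) covariance and the model-implied one.
#' Robust (scaled) variants are not implemented.
#'
#' @param model a [FittedFactorModel].
#' @param baseline output of [independenceModel()] on the same data; if
#'   `NULL` it is recomputed internally from the model's saturated fit
#'   statistics and `behavior` must be given.
#' @param behavior behavior matrix (needed when `baseline` is `NULL`).
#' @return named numeric vector `cfi`, `tli`, `rmsea`, `srmr`.
#' @export
fitIndices <- function(model, baseline = NULL, behavior = NULL) {
  if (is.null(baseline)) {
    if (is.null(behavior))
      stop("supply either a baseline model or the behavior matrix")
    baseline <- independenceModel(behavior, -2 * model@loglikSaturated)
  }
  chim <- model@chiSquare; dfm <- model@df
  chib <- baseline$chiSquare; dfb <- baseline$df
  n <- model@nUsed
  if (dfm == 0)
    stop("RMSEA/TLI undefined for a saturated model (df = 0)")
  cfi <- 1 - max(chim - dfm, 0) / max(chib - dfb, chim - dfm, 0)
  tli <- ((chib / dfb) - (chim / dfm)) / ((chib / dfb) - 1)
  rmsea <- sqrt(max(chim - dfm, 0) / (dfm * (n - 1)))

  S <- model@satSigma
  Simp <- model@loadings %*% model@factorCov %*% t(model@loadings) +
    model@residualCov
  d <- sqrt(diag(S))
  R <- (S - Simp) / tcrossprod(d)
  srmr <- sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  c(cfi = cfi, tli = tli, rmsea = rmsea, srmr = srmr)
}

#' Chi-square difference test for nested models
#'
#' Compares a restricted model against a full (less constrained) model
#' fitted to the same cases: `dChi = chi2_restricted - chi2_full` on
#' `ddf = df_restricted - df_full` degrees of freedom.
#'
#' @param modelRestricted,modelFull [FittedFactorModel] objects fitted
#'   to the same data.
#' @return list with `dChiSq`, `dDf`, `p`.
#' @export
chisqDiffTest <- function(modelRestricted, modelFull) {
  if (modelRestricted@nUsed != modelFull@nUsed)
    stop("models were fitted to different cases")
  dDf <- modelRestricted@df - modelFull@df
  if (dDf <= 0)
    stop("models are not nested as required (dDf <= 0)")
  dChi <- modelRestricted@chiSquare - modelFull@chiSquare
  list(dChiSq = dChi, dDf = dDf,
       p = stats::pchisq(max(dChi, 0), dDf, lower.tail = FALSE))
}

#' Omega hierarchical reliability per factor
#'
#' For a general factor, omega_h is the squared sum of its loadings over
#' the model-implied variance of the total score; for a group factor,
#' the same ratio restricted to that factor's indicators and their
#' subscale score. All variances are model-implied.
#'
#' @param model a [FittedFactorModel].
#' @return named numeric vector, one omega_h per factor.
#' @export
omegaHierarchical <- function(model) {
  L <- model@loadings
  Simp <- L %*% model@factorCov %*% t(L) + model@residualCov
  pat <- model@spec@pattern
  out <- numeric(ncol(L))
  names(out) <- colnames(L)
  for (f in seq_len(ncol(L))) {
    items <- which(pat[, f] == 1)
    if (length(items) < 2L)
      stop("omega_h undefined for factor '", colnames(L)[f],
           "' with < 2 indicators")
    num <- sum(L[items, f])^2
    den <- sum(Simp[items, items])
    out[f] <- num / den
  }
  out
}

#' Regression-method factor scores
#'
#' Maximum a posteriori (regression) scores computed from each
#' patient's observed test subset with model-implied covariances:
#' `eta = Phi Lambda_o' Sigma_oo^{-1} (y_o - mu_o)`. Patients with
#' missing entries receive finite scores from their observed subset; a
#' patient with no observed tests is an error.
#'
#' @param model a [FittedFactorModel].
#' @param behavior patients x tests matrix (`NA` allowed).
#' @return patients x factors score matrix.
#' @export
factorScores <- function(model, behavior) {
  spec <- model@spec
  if (!is.null(colnames(behavior)))
    behavior <- behavior[, spec@tests, drop = FALSE]
  if (any(rowSums(!is.na(behavior)) == 0L))
    stop("patient with zero observed tests cannot be scored")
  L <- model@loadings
  Phi <- model@factorCov
  Sigma <- L %*% Phi %*% t(L) + model@residualCov
  mu <- model@mu
  n <- nrow(behavior)
  scores <- matrix(NA_real_, n, ncol(L),
                   dimnames = list(rownames(behavior), colnames(L)))
  key <- apply(!is.na(behavior), 1L,
               function(z) paste(which(z), collapse = ","))
  for (k in unique(key)) {
    rows <- which(key == k)
    o <- as.integer(strsplit(k, ",")[[1]])
    W <- solve(Sigma[o, o, drop = FALSE])
    B <- Phi %*% t(L[o, , drop = FALSE]) %*% W
    Yc <- sweep(behavior[rows, o, drop = FALSE], 2L, mu[o])
    scores[rows, ] <- Yc %*% t(B)
  }
  scores
}
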