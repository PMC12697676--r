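#' @useDynLib gLDM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats cor cov optim pchisq pt qnorm rnorm runif sd var
#' @importFrom utils write.table read.delim head
NULL

## Deterministic child seeds: every analysis derives its own stream from
## the master seed plus a text tag, so stages are reproducible in isolation.
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435761)
  as.integer((abs(seed * 69069 + h)) %% 2147483587L) + 1L
}

## Evaluate expr under a local RNG state; the caller's stream is untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Pearson correlation of one vector against each column of a matrix.
colCor <- function(y, X) {
  yc <- y - mean(y)
  Xc <- sweep(X, 2L, colMeans(X))
  num <- as.vector(crossprod(Xc, yc))
  den <- sqrt(colSums(Xc^2) * sum(yc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

vthLargest <- function(x, v) {
  x <- sort(x, decreasing = TRUE)
  x[min(v, length(x))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
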