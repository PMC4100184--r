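## Shared numeric helpers. BETA_EPS is the single clipping constant used by
## every module that touches beta values (readers, generators, fitters).

BETA_EPS <- 1e-6

#' @noRd
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise log-sum-exp for a matrix of log-weights.
#' @noRd
rowLogSumExp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

#' @noRd
clipUnitInterval <- function(x, eps = BETA_EPS) {
  pmin(pmax(x, eps), 1 - eps)
}

## Validate a vector (or matrix rows) as unit l2 norm at `tol`; re-normalize
## when within tolerance, error otherwise.
#' @noRd
assertUnitRows <- function(X, tol = 1e-8, what = "input") {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  nrm <- sqrt(rowSums(X^2))
  bad <- which(abs(nrm - 1) > tol)
  if (length(bad)) {
    stop(sprintf("%s row(s) %s are not unit l2-norm vectors (tolerance %g)",
                 what, paste(utils::head(bad, 5L), collapse = ", "), tol))
  }
  X / nrm
}

#' @noRd
checkPositiveScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name))
  invisible(x)
}

## k-means++ seeding followed by stats::kmeans; returns hard labels.
#' @noRd
kmeansPPLabels <- function(X, k) {
  n <- nrow(X)
  if (k == 1L) return(rep(1L, n))
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2L:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers <- centers[!duplicated(round(centers, 12L)), , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 50L))
  as.integer(km$cluster)
}
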