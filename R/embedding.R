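## Preprocessing and linear/spectral dimension reduction: top-variance CpG
## selection, random-matrix-theory estimation of the signal dimension, PCA
## scores, and the normalized-affinity spectral embedding whose per-sample
## feature vectors have unit l2 norm.

#' Select the highest-variance features
#'
#' Keeps the `n` rows (CpGs) with the largest sample variance, preserving
#' the original row order among the selected; ties are broken by original
#' row order. Typical methylation-array practice keeps the top few thousand
#' CpGs before any model fitting.
#'
#' @param X \linkS4class{BetaValueMatrix} or numeric matrix (features x
#'   samples).
#' @param n number of rows to keep, 1 <= n <= nrow(X).
#' @return Object of the same class as `X` with `n` rows.
#' @export
selectTopVariance <- function(X, n) {
  mat <- if (is(X, "BetaValueMatrix")) betaValues(X) else as.matrix(X)
  if (n < 1 || n > nrow(mat))
    stop(sprintf("n must lie in [1, %d]", nrow(mat)))
  v <- apply(mat, 1L, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n)])
  X[keep, , drop = FALSE]
}

#' Estimate the signal dimension by random-matrix theory
#'
#' Standardizes each row (feature) to mean 0 and unit variance, forms the
#' T x T sample correlation matrix C = X'X / P, and counts eigenvalues above
#' the Marchenko-Pastur upper edge \eqn{(1 + \sqrt{T/P})^2} -- the largest
#' eigenvalue a pure-noise matrix of the same shape would asymptotically
#' produce. Constant rows are dropped with a warning.
#'
#' @param X \linkS4class{BetaValueMatrix} or numeric P x T matrix with at
#'   least 2 rows and 2 columns.
#' @return A \linkS4class{DimensionEstimate}.
#' @export
estimateDimRMT <- function(X) {
  mat <- if (is(X, "BetaValueMatrix")) betaValues(X) else as.matrix(X)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least a 2 x 2 matrix")
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant row(s)", sum(sds == 0)))
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  P <- nrow(mat); T <- ncol(mat)
  Z <- (mat - rowMeans(mat)) / sds
  C <- crossprod(Z) / P
  ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  edge <- (1 + sqrt(T / P))^2
  new("DimensionEstimate", K = sum(ev > edge), eigenvalues = ev,
      threshold = edge)
}

## Deterministic eigenvector orientation: largest-magnitude entry positive.
#' @noRd
fixSigns <- function(V) {
  s <- apply(V, 2L, function(v) sign(v[which.max(abs(v))]))
  sweep(V, 2L, ifelse(s == 0, 1, s), "*")
}

#' Principal-component scores
#'
#' Mean-centers each feature (row) and projects the samples onto the K
#' leading eigenvectors of the feature covariance matrix.
#'
#' @param X \linkS4class{BetaValueMatrix} or numeric P x T matrix (features
#'   x samples).
#' @param K number of components, 1 <= K <= min(P, T).
#' @return K x T score matrix (components x samples).
#' @export
pcaReduce <- function(X, K) {
  mat <- if (is(X, "BetaValueMatrix")) betaValues(X) else as.matrix(X)
  if (K < 1 || K > min(dim(mat)))
    stop(sprintf("K must lie in [1, %d]", min(dim(mat))))
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  rot <- fixSigns(pc$rotation[, seq_len(K), drop = FALSE])
  centered <- mat - rowMeans(mat)
  scores <- crossprod(rot, centered)           # K x T
  dimnames(scores) <- list(sprintf("PC%d", seq_len(K)), colnames(mat))
  scores
}

#' Spectral embedding with unit-norm sample features
#'
#' Implements the normalized-affinity spectral feature extraction: affinity
#' \eqn{A_{ij} = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))} with zero diagonal
#' over the N column-samples, \eqn{M = D^{-1/2} A D^{-1/2}} with D the
#' diagonal of row sums, the K leading eigenvectors of M stacked as rows of
#' Y (K x N), and each column of Y scaled to unit l2 norm to give Z. With
#' `sigma = "auto"`, \eqn{\sigma} is the square root of the variance of the
#' entries of the squared-distance matrix \eqn{B_{ij} = \|x_i - x_j\|^2}.
#'
#' @param X numeric matrix whose columns are the N samples (rows are
#'   feature dimensions), or a \linkS4class{BetaValueMatrix}.
#' @param K embedding dimension, 1 <= K <= N.
#' @param sigma positive kernel width, or "auto" (default).
#' @return K x N matrix of class-checked unit-column features (each column
#'   has l2 norm 1 within 1e-10).
#' @export
spectralEmbed <- function(X, K, sigma = "auto") {
  mat <- if (is(X, "BetaValueMatrix")) betaValues(X) else as.matrix(X)
  N <- ncol(mat)
  if (K < 1 || K > N) stop(sprintf("K must lie in [1, N = %d]", N))
  B <- as.matrix(stats::dist(t(mat)))^2
  if (identical(sigma, "auto")) {
    sigma <- sqrt(stats::var(as.vector(B)))
    if (sigma == 0) stop("degenerate data: all pairwise distances equal")
  }
  checkPositiveScalar(sigma, "sigma")
  A <- exp(-B / (2 * sigma^2))
  diag(A) <- 0
  d <- rowSums(A)
  if (any(d <= 0)) {
    iso <- colnames(mat)[which(d <= 0)[1L]]
    stop(sprintf("sample '%s' is isolated (zero affinity row sum)",
                 if (is.null(iso)) as.character(which(d <= 0)[1L]) else iso))
  }
  M <- A / sqrt(tcrossprod(d))
  V <- fixSigns(eigen(M, symmetric = TRUE)$vectors[, seq_len(K),
                                                   drop = FALSE])
  Y <- t(V)                      # K x N: eigenvectors as rows
  Z <- sweep(Y, 2L, sqrt(colSums(Y^2)), "/")
  dimnames(Z) <- list(sprintf("SC%d", seq_len(K)), colnames(mat))
  Z
}
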