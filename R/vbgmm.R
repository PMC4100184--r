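## Variational Bayesian Gaussian mixture model: the Gaussian baseline the
## non-Gaussian clusterers are compared against. Conjugate
## Gaussian-Wishart posteriors per component, sparse Dirichlet prior on the
## weights, pruning of low-weight components.

#' Fit a variational Bayesian Gaussian mixture model
#'
#' Baseline clusterer for real-valued embeddings (e.g. PCA scores). The
#' feature matrix follows the components-by-samples convention of the
#' embedding functions: `Y` is K x N with one column per sample. Requires
#' more samples than feature dimensions; otherwise the component covariances
#' are singular and the fit refuses with advice to reduce the dimension.
#'
#' @param Y numeric K x N feature matrix (rows = dimensions, columns =
#'   samples).
#' @param Minit initial number of mixture components (default 10).
#' @param prune weight threshold below which a component is removed
#'   (default 0.01).
#' @param seed integer seed for the k-means++ initializations.
#' @param maxIter,tol convergence controls.
#' @return A \linkS4class{MixtureFit} with family "gaussian"; `params`
#'   holds per-component posterior parameters (m, beta, W, nu).
#' @export
fitVBGMM <- function(Y, Minit = 10L, prune = 0.01, seed = 1L,
                     maxIter = 500L, tol = 1e-6) {
  Y <- as.matrix(Y)
  X <- t(Y)                              # N x D internally
  N <- nrow(X); D <- ncol(X)
  if (N <= D)
    stop("need more samples than feature dimensions; reduce the dimension first")
  ## priors: vague mean at the data centroid, covariance scale from the data
  m0 <- colMeans(X); beta0 <- 1; nu0 <- D + 2
  W0inv <- diag(pmax(apply(X, 2L, stats::var), 1e-8), D)
  lnBWishart <- function(Winv, nu) {
    ## log normalizer B(W, nu) of the Wishart, parameterized by W^{-1}
    0.5 * nu * determinant(Winv, logarithm = TRUE)$modulus -
      0.5 * nu * D * log(2) - 0.25 * D * (D - 1) * log(pi) -
      sum(lgamma(0.5 * (nu + 1 - seq_len(D))))
  }
  ElnDetLambda <- function(Winv, nu)
    sum(digamma(0.5 * (nu + 1 - seq_len(D)))) + D * log(2) -
      determinant(Winv, logarithm = TRUE)$modulus
  klNW <- function(m, beta, Winv, nu) {
    ## KL(q(mu, Lambda) || prior), Gaussian-Wishart vs Gaussian-Wishart
    W <- solve(Winv)
    ElnDet <- ElnDetLambda(Winv, nu)
    klN <- 0.5 * (D * beta0 / beta - D + D * log(beta / beta0) +
                    beta0 * nu * drop(t(m - m0) %*% W %*% (m - m0)))
    klW <- 0.5 * (nu - nu0) * ElnDet -
      0.5 * sum(diag((Winv - W0inv) %*% (nu * W))) +
      lnBWishart(Winv, nu) - lnBWishart(W0inv, nu0)
    as.numeric(klN + klW)
  }

  cavi <- function(Yin, R) {
    M <- ncol(R)
    elbo <- numeric(0)
    qs <- NULL
    for (it in seq_len(maxIter)) {
      Nk <- pmax(colSums(R), 1e-10)
      ds <- dirichletStats(colSums(R))
      qs <- vector("list", M)
      for (m in seq_len(M)) {
        w <- R[, m]
        xbar <- colSums(w * X) / Nk[m]
        Xc <- X - rep(xbar, each = N)
        Sk <- crossprod(Xc * sqrt(w)) / Nk[m]
        beta <- beta0 + Nk[m]
        mk <- (beta0 * m0 + Nk[m] * xbar) / beta
        nu <- nu0 + Nk[m]
        d0 <- xbar - m0
        Winv <- W0inv + Nk[m] * Sk +
          (beta0 * Nk[m] / beta) * tcrossprod(d0)
        qs[[m]] <- list(m = mk, beta = beta, Winv = Winv, nu = nu)
      }
      logRho <- matrix(0, N, M)
      klq <- 0
      for (m in seq_len(M)) {
        q <- qs[[m]]
        W <- solve(q$Winv)
        ElnDet <- ElnDetLambda(q$Winv, q$nu)
        Xm <- X - rep(q$m, each = N)
        quad <- D / q$beta + q$nu * rowSums((Xm %*% W) * Xm)
        logRho[, m] <- ds$ElnPi[m] + 0.5 * ElnDet -
          0.5 * D * log(2 * pi) - 0.5 * quad
        klq <- klq + klNW(q$m, q$beta, q$Winv, q$nu)
      }
      nr <- normalizeLogResp(logRho)
      R <- nr$R
      elbo <- c(elbo, nr$sumLse - dirichletKL(ds$alpha) - klq)
      if (it >= 2L &&
          abs(elbo[it] - elbo[it - 1L]) <
            tol * (abs(elbo[it - 1L]) + 1e-12)) break
    }
    list(R = R, elbo = elbo, params = qs, weights = colSums(R) / N)
  }

  fit <- vbDriver(X, Minit, prune, seed, cavi)
  buildMixtureFit("gaussian", fit)
}
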