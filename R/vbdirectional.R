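## Directional mixture models for unit-norm features (spectral embeddings):
## von Mises-Fisher components for directional data, Watson components for
## axial data (x and -x equivalent). Both use a variational posterior over
## labels and a sparse Dirichlet posterior over weights; component
## directions and concentrations are point-estimated at their posterior
## modes (uniform prior on the sphere for the direction, weak gamma prior
## on the concentration), with the concentration update solved exactly as a
## 1-D concave root-finding problem so the traced bound stays monotone.

## weak gamma prior on concentrations; shape 1 leaves the update linear
KAPPA_PRIOR_RATE <- 0.01
KAPPA_MAX <- 2000

## Solve S - Nm * A_K(lambda) - b0 = 0 for the vMF concentration, where
## A_K(lambda) = I_{K/2}(lambda) / I_{K/2-1}(lambda) is increasing on
## (0, Inf); the weighted log-likelihood is concave in lambda.
#' @noRd
solveVmfKappa <- function(S, Nm, K) {
  f <- function(l) {
    r <- besselI(l, K / 2, expon.scaled = TRUE) /
      besselI(l, K / 2 - 1, expon.scaled = TRUE)
    S - Nm * r - KAPPA_PRIOR_RATE
  }
  if (f(1e-6) <= 0) return(1e-6)
  if (f(KAPPA_MAX) >= 0) return(KAPPA_MAX)
  stats::uniroot(f, c(1e-6, KAPPA_MAX), tol = 1e-8)$root
}

## Watson analogue: S2 - Nm * W(kappa) - b0 = 0 with
## W(kappa) = d/dkappa ln 1F1(1/2, p/2, kappa), increasing from 1/p to 1.
#' @noRd
solveWatsonKappa <- function(S2, Nm, p) {
  f <- function(k) S2 - Nm * kummerRatio(0.5, p / 2, k) - KAPPA_PRIOR_RATE
  if (f(1e-3) <= 0) return(1e-3)
  if (f(KAPPA_MAX) >= 0) return(KAPPA_MAX)
  stats::uniroot(f, c(1e-3, KAPPA_MAX), tol = 1e-8)$root
}

#' @noRd
directionalCavi <- function(Z, family, maxIter, tol) {
  N <- nrow(Z); K <- ncol(Z)
  function(Y, R) {
    M <- ncol(R)
    elbo <- numeric(0)
    qs <- NULL
    for (it in seq_len(maxIter)) {
      ds <- dirichletStats(colSums(R))
      qs <- vector("list", M)
      for (m in seq_len(M)) {
        w <- R[, m]
        Nm <- sum(w)
        if (family == "vmf") {
          rbar <- colSums(w * Z)
          mu <- if (sum(rbar^2) > 0) rbar / sqrt(sum(rbar^2)) else
            c(1, rep(0, K - 1))
          kap <- solveVmfKappa(sqrt(sum(rbar^2)), Nm, K)
        } else {
          Sc <- crossprod(Z * sqrt(w))
          eg <- eigen(Sc, symmetric = TRUE)
          mu <- eg$vectors[, 1L]
          mu <- mu * sign(mu[which.max(abs(mu))])
          kap <- solveWatsonKappa(eg$values[1L], Nm, K)
        }
        qs[[m]] <- list(mu = mu, kappa = kap)
      }
      logRho <- matrix(0, N, M)
      lprior <- 0
      for (m in seq_len(M)) {
        q <- qs[[m]]
        logRho[, m] <- ds$ElnPi[m] +
          if (family == "vmf")
            vmfLogNormalizer(K, q$kappa) + q$kappa * drop(Z %*% q$mu)
          else
            lgamma(K / 2) - log(2) - (K / 2) * log(pi) -
              logKummer(0.5, K / 2, q$kappa) +
              q$kappa * drop(Z %*% q$mu)^2
        lprior <- lprior - KAPPA_PRIOR_RATE * q$kappa
      }
      nr <- normalizeLogResp(logRho)
      R <- nr$R
      elbo <- c(elbo, nr$sumLse - dirichletKL(ds$alpha) + lprior)
      if (it >= 2L &&
          abs(elbo[it] - elbo[it - 1L]) <
            tol * (abs(elbo[it - 1L]) + 1e-12)) break
    }
    list(R = R, elbo = elbo, params = qs, weights = colSums(R) / N)
  }
}

#' Fit a variational von Mises-Fisher mixture model
#'
#' Clusters unit-norm feature vectors (one per row) on the hypersphere,
#' e.g. the columns of a spectral embedding. Component count is selected
#' automatically through the sparse Dirichlet weight posterior plus
#' pruning.
#'
#' @param Z numeric N x K matrix whose rows are unit l2-norm vectors
#'   (re-normalized if within 1e-8, rejected otherwise).
#' @param Minit initial number of components (default 10).
#' @param prune weight threshold for component removal (default 0.01).
#' @param seed integer seed for the k-means++ initializations.
#' @param maxIter,tol convergence controls.
#' @return A \linkS4class{MixtureFit} with family "vmf"; `params` holds
#'   per-component `mu` (unit mean direction) and `kappa`.
#' @export
fitVBVMM <- function(Z, Minit = 10L, prune = 0.01, seed = 1L,
                     maxIter = 500L, tol = 1e-6) {
  Z <- assertUnitRows(as.matrix(Z), what = "Z")
  cavi <- directionalCavi(Z, "vmf", maxIter, tol)
  buildMixtureFit("vmf", vbDriver(Z, Minit, prune, seed, cavi))
}

#' Fit a variational Watson mixture model
#'
#' Clusters axial unit-norm data, where x and -x are the same observation:
#' every quantity the fit touches depends on the data only through outer
#' products and squared projections, so assignments are exactly invariant
#' to sign flips of any input vector. Components are restricted to positive
#' concentration (clusters around an axis).
#'
#' @inheritParams fitVBVMM
#' @return A \linkS4class{MixtureFit} with family "watson"; `params` holds
#'   per-component `mu` (unit mean axis) and `kappa` (> 0).
#' @export
fitVBWMM <- function(Z, Minit = 10L, prune = 0.01, seed = 1L,
                     maxIter = 500L, tol = 1e-6) {
  Z <- assertUnitRows(as.matrix(Z), what = "Z")
  ## canonical sign per observation so the k-means++ initialization is
  ## sign-invariant too: orient each row by its largest-magnitude entry
  Zc <- t(apply(Z, 1L, function(z) z * sign(z[which.max(abs(z))])))
  cavi <- directionalCavi(Z, "watson", maxIter, tol)
  buildMixtureFit("watson", vbDriver(Zc, Minit, prune, seed, cavi))
}
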