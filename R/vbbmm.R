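## Variational Bayesian beta mixture model (VBBMM) for bounded features.
## Each component is a product of independent beta laws over the K feature
## dimensions; gamma priors sit on every beta shape parameter and a sparse
## Dirichlet prior on the mixture weights, so redundant components collapse
## and are pruned. The intractable E[lnG(u+v) - lnG(u) - lnG(v)] is handled
## by the same relative-convexity bound as the factorization module
## (extended variational inference), keeping every factor gamma with
## closed-form shape/rate updates.

## gamma hyperpriors on the beta shapes
VBBMM_PRIOR <- list(shape = 1, rate = 0.1)

#' Fit a variational Bayesian beta mixture model
#'
#' Clusters N observations with K bounded feature dimensions (entries
#' strictly inside (0, 1), e.g. the rows of a BG-NMF pseudo-basis). Model
#' complexity is determined automatically: the fit starts from `Minit`
#' components (default 15) and removes components whose posterior weight
#' falls below `prune` (default 0.01).
#'
#' @param Y numeric N x K matrix with entries in (0, 1); exact 0/1 raise an
#'   error instructing the caller to clip.
#' @param Minit initial number of mixture components.
#' @param prune weight threshold below which a component is removed.
#' @param seed integer seed controlling the k-means++ initializations.
#' @param maxIter,tol convergence controls for each coordinate-ascent run.
#' @return A \linkS4class{MixtureFit} with family "beta"; `params` holds
#'   per-component posterior-mean shape vectors `u`, `v` and the gamma
#'   posteriors they derive from.
#' @examples
#' sim <- simulateGroupMethylation(P = 60, T = 90,
#'                                 groupSizes = c(30, 30, 30), seed = 2)
#' fit <- fitVBBMM(t(betaValues(sim$X))[, 1:5], Minit = 8, seed = 1)
#' nComponents(fit)
#' @export
fitVBBMM <- function(Y, Minit = 15L, prune = 0.01, seed = 1L,
                     maxIter = 500L, tol = 1e-6) {
  Y <- as.matrix(Y)
  if (any(Y <= 0 | Y >= 1))
    stop("Y contains values at or beyond 0/1; clip into [1e-6, 1 - 1e-6] first")
  N <- nrow(Y); K <- ncol(Y)
  LX <- log(Y); L1X <- log1p(-Y)
  pr <- VBBMM_PRIOR

  cavi <- function(Y, R) {
    M <- ncol(R)
    ## moment-matched initialization of the gamma posteriors from R
    qs <- vector("list", M)
    for (m in seq_len(M)) {
      w <- R[, m]
      mm <- colSums(w * Y) / sum(w)
      s2 <- pmax(colSums(w * (Y - rep(mm, each = N))^2) / sum(w), 1e-5)
      cc <- pmin(pmax(mm * (1 - mm) / s2 - 1, 0.2), 1e3)
      qs[[m]] <- list(au = 2 * pmax(mm * cc, 0.05), bu = rep(2, K),
                      av = 2 * pmax((1 - mm) * cc, 0.05), bv = rep(2, K))
    }
    elbo <- numeric(0)
    for (it in seq_len(maxIter)) {
      Nk <- colSums(R)
      ds <- dirichletStats(Nk)
      ## M-step: gamma posteriors per component and dimension
      for (m in seq_len(M)) {
        q <- qs[[m]]
        ubar <- q$au / q$bu; vbar <- q$av / q$bv
        gap_u <- digamma(ubar + vbar) - digamma(ubar)
        gap_v <- digamma(ubar + vbar) - digamma(vbar)
        w <- R[, m]
        qs[[m]] <- list(
          au = pr$shape + ubar * gap_u * sum(w),
          bu = pr$rate - colSums(w * LX),
          av = pr$shape + vbar * gap_v * sum(w),
          bv = pr$rate - colSums(w * L1X))
      }
      ## E-step: expected log-density under the anchored bound
      logRho <- matrix(0, N, M)
      klq <- 0
      for (m in seq_len(M)) {
        q <- qs[[m]]
        ubar <- q$au / q$bu; vbar <- q$av / q$bv
        g0 <- lgamma(ubar + vbar) - lgamma(ubar) - lgamma(vbar)
        corr <- ubar * (digamma(ubar + vbar) - digamma(ubar)) *
          (digamma(q$au) - log(q$au)) +
          vbar * (digamma(ubar + vbar) - digamma(vbar)) *
          (digamma(q$av) - log(q$av))
        logRho[, m] <- ds$ElnPi[m] + sum(g0 + corr) +
          LX %*% (ubar - 1) + L1X %*% (vbar - 1)
        klq <- klq + sum(gammaKL(q$au, q$bu, pr$shape, pr$rate)) +
          sum(gammaKL(q$av, q$bv, pr$shape, pr$rate))
      }
      nr <- normalizeLogResp(logRho)
      R <- nr$R
      elbo <- c(elbo, nr$sumLse - dirichletKL(ds$alpha) - klq)
      if (it >= 2L &&
          abs(elbo[it] - elbo[it - 1L]) <
            tol * (abs(elbo[it - 1L]) + 1e-12)) break
    }
    params <- lapply(qs, function(q)
      list(u = q$au / q$bu, v = q$av / q$bv, q = q))
    list(R = R, elbo = elbo, params = params, weights = colSums(R) / N)
  }

  fit <- vbDriver(Y, Minit, prune, seed, cavi)
  buildMixtureFit("beta", fit)
}
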