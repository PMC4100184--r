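## Beta-gamma nonnegative matrix factorization (BG-NMF) for bounded-support
## data. Each observation X_pt in (0,1) is beta-distributed with shape
## parameters a_pt = sum_k A_pk H_kt and b_pt = sum_k B_pk H_kt; the entries
## of the basis matrices A, B and the shared excitation matrix H carry gamma
## priors. Inference is extended variational Bayes with all factors gamma:
## the intractable E[lnG(a+b) - lnG(a) - lnG(b)] is handled by a
## relative-convexity (tangent in log space) lower bound anchored at the
## current posterior means, and E[ln sum_k A_pk H_kt] by a Jensen bound with
## weights proportional to the mean summands. Both bounds are tight at the
## anchor, which yields closed-form shape/rate updates and a monotone
## ELBO-surrogate.

#' @noRd
defaultBGNMFPriors <- function() {
  list(mu0 = 1, alpha0 = 1, nu0 = 1, beta0 = 1, rho0 = 0.5, zeta0 = 1)
}

## KL(Gamma(shape a, rate b) || Gamma(a0, b0)), vectorized.
#' @noRd
gammaKL <- function(a, b, a0, b0) {
  (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
}

## Anchored lower bound on the expected beta log-likelihood plus negative
## KL terms; the quantity reported in elboTrace().
#' @noRd
bgnmfElbo <- function(st, LX, L1X, pr) {
  Abar <- st$Ashape / st$Arate; Bbar <- st$Bshape / st$Brate
  Hbar <- st$Hshape / st$Hrate
  a <- Abar %*% Hbar; b <- Bbar %*% Hbar
  dgab <- digamma(a + b)
  PsiA <- dgab - digamma(a); PsiB <- dgab - digamma(b)
  dA <- digamma(st$Ashape) - log(st$Ashape)
  dB <- digamma(st$Bshape) - log(st$Bshape)
  dH <- digamma(st$Hshape) - log(st$Hshape)
  CA <- (Abar * dA) %*% Hbar + Abar %*% (Hbar * dH)
  CB <- (Bbar * dB) %*% Hbar + Bbar %*% (Hbar * dH)
  elik <- sum(lgamma(a + b) - lgamma(a) - lgamma(b) +
                PsiA * CA + PsiB * CB +
                (a - 1) * LX + (b - 1) * L1X)
  elik -
    sum(gammaKL(st$Ashape, st$Arate, pr$mu0, pr$alpha0)) -
    sum(gammaKL(st$Bshape, st$Brate, pr$nu0, pr$beta0)) -
    sum(gammaKL(st$Hshape, st$Hrate, pr$rho0, pr$zeta0))
}

#' Fit the beta-gamma nonnegative matrix factorization
#'
#' Factorizes a bounded matrix X (P features x T samples, entries in (0,1))
#' through the generative model A_pk ~ Gamma(mu0, alpha0),
#' B_pk ~ Gamma(nu0, beta0), H_kt ~ Gamma(rho0, zeta0),
#' X_pt ~ Beta(sum_k A_pk H_kt, sum_k B_pk H_kt), returning gamma
#' variational posteriors for every entry of A, B and H. A sub-unit prior
#' shape on H (default rho0 = 0.5) realizes the sparsity constraint on the
#' excitation columns. To reduce samples (not features), pass the transpose:
#' fitting a samples x CpGs matrix yields a samples x K pseudo-basis.
#'
#' The per-sweep update order is A, B, H, with the bound anchors (posterior
#' means) refreshed after each block; the fit stops when the relative change
#' of the ELBO surrogate drops below `tol` or after `maxIter` sweeps.
#' Initialization is deterministic given `seed`: excitation means from
#' scaled nonnegative random draws (column sums 1), basis means from
#' moment-matching per-row beta fits of X.
#'
#' @param X \linkS4class{BetaValueMatrix} or numeric P x T matrix with
#'   entries strictly inside (0, 1); values at exactly 0/1 raise an error
#'   instructing the caller to clip.
#' @param K inner dimension, 1 <= K <= min(P, T).
#' @param priors named list of positive gamma hyperparameters
#'   (mu0, alpha0, nu0, beta0, rho0, zeta0); see defaults above.
#' @param maxIter maximum number of sweeps (default 500).
#' @param tol relative ELBO-surrogate change declaring convergence
#'   (default 1e-5).
#' @param seed integer seed for the initialization.
#' @return A \linkS4class{BGNMFFit}.
#' @examples
#' X <- matrix(runif(50 * 8, 0.2, 0.8), 50, 8)
#' fit <- fitBGNMF(X, K = 2, maxIter = 50, seed = 1)
#' range(reconstructMean(fit))
#' @seealso [reconstructMean()], [pseudoBasis()], [simulateBGNMFMatrix()]
#' @export
fitBGNMF <- function(X, K, priors = defaultBGNMFPriors(),
                     maxIter = 500L, tol = 1e-5, seed = 1L) {
  if (is(X, "BetaValueMatrix")) X <- betaValues(X)
  X <- as.matrix(X)
  P <- nrow(X); T <- ncol(X)
  if (K < 1 || K > min(P, T))
    stop(sprintf("K must lie in [1, min(P, T)] = [1, %d]", min(P, T)))
  if (any(X <= 0 | X >= 1))
    stop("X contains values at or beyond 0/1; clip into [1e-6, 1 - 1e-6] first")
  pr <- utils::modifyList(defaultBGNMFPriors(), as.list(priors))
  for (nm in names(defaultBGNMFPriors())) checkPositiveScalar(pr[[nm]], nm)
  K <- as.integer(K)
  LX <- log(X); L1X <- log1p(-X)

  st <- withr::with_seed(as.integer(seed), {
    ## moment-matched per-row beta shapes
    m <- rowMeans(X)
    s2 <- pmax(apply(X, 1L, stats::var), 1e-6)
    cc <- pmin(pmax(m * (1 - m) / s2 - 1, 0.2), 1e3)
    u <- pmin(pmax(m * cc, 0.1), 1e3)
    v <- pmin(pmax((1 - m) * cc, 0.1), 1e3)
    jitter <- function(n) stats::runif(n, 0.7, 1.3)
    H0 <- matrix(stats::runif(K * T, 0.1, 1), K, T)
    H0 <- sweep(H0, 2L, colSums(H0), "/")
    A0 <- matrix(u, P, K) * matrix(jitter(P * K), P, K)
    B0 <- matrix(v, P, K) * matrix(jitter(P * K), P, K)
    list(Ashape = 2 * A0, Arate = matrix(2, P, K),
         Bshape = 2 * B0, Brate = matrix(2, P, K),
         Hshape = 2 * H0, Hrate = matrix(2, K, T))
  })

  psiGaps <- function() {
    Abar <- st$Ashape / st$Arate; Bbar <- st$Bshape / st$Brate
    Hbar <- st$Hshape / st$Hrate
    a <- Abar %*% Hbar; b <- Bbar %*% Hbar
    dgab <- digamma(a + b)
    list(Abar = Abar, Bbar = Bbar, Hbar = Hbar,
         PsiA = dgab - digamma(a), PsiB = dgab - digamma(b))
  }

  elbo <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    g <- psiGaps()
    st$Ashape <- pr$mu0 + g$Abar * (g$PsiA %*% t(g$Hbar))
    st$Arate <- pr$alpha0 - LX %*% t(g$Hbar)
    g <- psiGaps()
    st$Bshape <- pr$nu0 + g$Bbar * (g$PsiB %*% t(g$Hbar))
    st$Brate <- pr$beta0 - L1X %*% t(g$Hbar)
    g <- psiGaps()
    st$Hshape <- pr$rho0 + g$Hbar * (t(g$Abar) %*% g$PsiA +
                                       t(g$Bbar) %*% g$PsiB)
    st$Hrate <- pr$zeta0 - (t(g$Abar) %*% LX + t(g$Bbar) %*% L1X)
    elbo <- c(elbo, bgnmfElbo(st, LX, L1X, pr))
    if (it >= 2L) {
      rel <- abs(elbo[it] - elbo[it - 1L]) /
        (abs(elbo[it - 1L]) + .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
  }

  dn <- function(M, rn, cn) { dimnames(M) <- list(rn, cn); M }
  kn <- sprintf("k%02d", seq_len(K))
  new("BGNMFFit",
      Ashape = dn(st$Ashape, rownames(X), kn),
      Arate = dn(st$Arate, rownames(X), kn),
      Bshape = dn(st$Bshape, rownames(X), kn),
      Brate = dn(st$Brate, rownames(X), kn),
      Hshape = dn(st$Hshape, kn, colnames(X)),
      Hrate = dn(st$Hrate, kn, colnames(X)),
      elbo = elbo, K = K, iterations = it, converged = converged)
}

#' @describeIn fitBGNMF posterior-mean reconstruction
#'   \eqn{\bar X = \bar A \bar H \oslash (\bar A \bar H + \bar B \bar H)};
#'   every entry lies strictly in (0, 1).
#' @param object a \linkS4class{BGNMFFit}
#' @export
setMethod("reconstructMean", "BGNMFFit", function(object) {
  aa <- (object@Ashape / object@Arate) %*% (object@Hshape / object@Hrate)
  bb <- (object@Bshape / object@Brate) %*% (object@Hshape / object@Hrate)
  aa / (aa + bb)
})

#' @describeIn fitBGNMF bounded pseudo-basis
#'   \eqn{\bar W = \bar A \oslash (\bar A + \bar B)} with the excitation
#'   matrix \eqn{\bar H}.
#' @export
setMethod("pseudoBasis", "BGNMFFit", function(object) {
  Abar <- object@Ashape / object@Arate
  Bbar <- object@Bshape / object@Brate
  new("PseudoBasis", W = Abar / (Abar + Bbar),
      H = object@Hshape / object@Hrate)
})
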