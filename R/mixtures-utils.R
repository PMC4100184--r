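## Shared machinery for the variational mixture fitters: sparse-Dirichlet
## weight posteriors, seeded k-means++ initialization with restarts, and the
## converge -> prune -> refit driver. All fitters share the defaults
## pruneThreshold = 0.01 and a sparse Dirichlet concentration of 1e-3, which
## drives redundant components towards zero weight so that pruning can
## remove them.

DIRICHLET_C0 <- 1e-3

#' @noRd
dirichletStats <- function(Nk, c0 = DIRICHLET_C0) {
  alpha <- c0 + Nk
  list(alpha = alpha,
       ElnPi = digamma(alpha) - digamma(sum(alpha)))
}

## KL(Dir(alpha) || Dir(c0, ..., c0))
#' @noRd
dirichletKL <- function(alpha, c0 = DIRICHLET_C0) {
  M <- length(alpha)
  a0 <- rep(c0, M)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * (digamma(alpha) - digamma(sum(alpha))))
}

## Normalize log-responsibilities; returns the row-stochastic matrix and
## sum of log-sum-exps (the collapsed E[ln p] + entropy term of the ELBO).
#' @noRd
normalizeLogResp <- function(logRho) {
  lse <- rowLogSumExp(logRho)
  list(R = exp(logRho - lse), sumLse = sum(lse))
}

## Responsibility matrix from hard labels (one-hot with a small floor so
## every component owns a little mass initially).
#' @noRd
labelsToResp <- function(labels, M, floor = 1e-3) {
  N <- length(labels)
  R <- matrix(floor, N, M)
  R[cbind(seq_len(N), labels)] <- 1
  R / rowSums(R)
}

## Generic driver: `cavi(Y, R0)` must run coordinate ascent to convergence
## from initial responsibilities R0 and return list(R, elbo, params,
## weights). The driver runs seeded k-means++ restarts at the requested
## initial component count plus a ladder of smaller counts (coordinate
## ascent cannot merge symmetric redundant components on weakly structured
## data, so parsimonious solutions must be reachable from their own
## starts), keeps the run with the best final ELBO, prunes components below
## `prune`, and runs one refit pass.
#' @noRd
vbDriver <- function(Y, Minit, prune, seed, cavi, restarts = 3L) {
  N <- nrow(Y)
  Minit <- min(Minit, N)
  Ms <- c(rep(Minit, restarts),
          setdiff(unique(c(1L, 2L, max(1L, Minit %/% 2L))), Minit))
  best <- NULL
  for (r in seq_along(Ms)) {
    lab <- withr::with_seed(as.integer(seed) + 1000L * (r - 1L),
                            kmeansPPLabels(Y, Ms[r]))
    fit <- cavi(Y, labelsToResp(lab, Ms[r]))
    if (is.null(best) ||
        utils::tail(fit$elbo, 1L) > utils::tail(best$elbo, 1L))
      best <- fit
  }
  keep <- which(best$weights >= prune)
  if (length(keep) == 0L) keep <- which.max(best$weights)
  if (length(keep) < length(best$weights)) {
    R0 <- best$R[, keep, drop = FALSE]
    R0 <- R0 / rowSums(R0)
    ## the returned trace is the refit's own: pruning changes the model
    ## structure, so traces are not comparable across the prune boundary
    refit <- cavi(Y, R0)
    best <- refit
    ## final report drops any component that fell below threshold during
    ## the refit (no further refit pass)
    keep2 <- which(best$weights >= prune)
    if (length(keep2) == 0L) keep2 <- which.max(best$weights)
    if (length(keep2) < length(best$weights)) {
      best$R <- best$R[, keep2, drop = FALSE]
      best$R <- best$R / rowSums(best$R)
      best$weights <- best$weights[keep2] / sum(best$weights[keep2])
      best$params <- best$params[keep2]
    }
  }
  best
}

#' @noRd
buildMixtureFit <- function(family, fit, elboKeep = TRUE) {
  M <- length(fit$weights)
  new("MixtureFit", family = family,
      weights = fit$weights / sum(fit$weights),
      params = fit$params,
      responsibilities = fit$R,
      labels = as.integer(apply(fit$R, 1L, which.max)),
      Meffective = as.integer(M),
      elbo = if (elboKeep) fit$elbo else numeric(0),
      extras = if (is.null(fit$extras)) list() else fit$extras)
}

## Weighted independent-beta maximum likelihood for one component:
## maximizes sum_n w_n sum_k ln Beta(x_nk; u_k, v_k) dimension by dimension
## (L-BFGS-B on log-shapes with analytic gradient, moment-matched start).
#' @noRd
weightedBetaMLE <- function(X, w) {
  K <- ncol(X)
  W <- sum(w)
  u <- numeric(K); v <- numeric(K)
  for (k in seq_len(K)) {
    x <- X[, k]
    Slx <- sum(w * log(x)); Sl1x <- sum(w * log1p(-x))
    m <- sum(w * x) / W
    s2 <- max(sum(w * (x - m)^2) / W, 1e-6)
    cc <- min(max(m * (1 - m) / s2 - 1, 0.2), 1e4)
    par0 <- log(pmin(pmax(c(m * cc, (1 - m) * cc), 0.05), 1e4))
    nll <- function(p) {
      uu <- exp(p[1L]); vv <- exp(p[2L])
      -(W * (lgamma(uu + vv) - lgamma(uu) - lgamma(vv)) +
          (uu - 1) * Slx + (vv - 1) * Sl1x)
    }
    gnll <- function(p) {
      uu <- exp(p[1L]); vv <- exp(p[2L])
      dgs <- digamma(uu + vv)
      -c(uu * (W * (dgs - digamma(uu)) + Slx),
         vv * (W * (dgs - digamma(vv)) + Sl1x))
    }
    opt <- stats::optim(par0, nll, gnll, method = "L-BFGS-B",
                        lower = log(1e-3), upper = log(1e5))
    u[k] <- exp(opt$par[1L]); v[k] <- exp(opt$par[2L])
  }
  list(u = u, v = v)
}
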