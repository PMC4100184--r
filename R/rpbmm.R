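## Recursive partitioning beta mixture model (RPBMM): the benchmark
## clusterer. Starting from the root node holding all samples, each node
## fits a 1-component and a 2-component independent-beta mixture by
## (weighted) EM and splits iff the responsibility-weighted BIC improves;
## the leaves of the resulting binary tree are the final clusters, labeled
## by their split path (root "r", then "L"/"R" per split).

#' @noRd
betaLogLikMatrix <- function(X, u, v) {
  ## N x 1 vector of independent-beta log-densities with shape vectors u, v
  drop(log(X) %*% (u - 1) + log1p(-X) %*% (v - 1)) +
    sum(lgamma(u + v) - lgamma(u) - lgamma(v))
}

## Weighted 2-component independent-beta mixture by EM; returns weighted
## log-likelihood and responsibilities.
#' @noRd
betaMixEM2 <- function(X, w, maxIter = 100L, tol = 1e-6) {
  N <- nrow(X)
  ## initialize from the node's own members (high weight), then assign the
  ## rest to the nearest center -- an unweighted k-means would rediscover
  ## the parent split instead of structure within this node
  core <- which(w >= 0.5 * max(w))
  if (length(core) >= 4L) {
    labCore <- kmeansPPLabels(X[core, , drop = FALSE], 2L)
    ctr <- rbind(colMeans(X[core[labCore == 1L], , drop = FALSE]),
                 colMeans(X[core[labCore == 2L], , drop = FALSE]))
    d1 <- rowSums((X - rep(ctr[1L, ], each = N))^2)
    d2 <- rowSums((X - rep(ctr[2L, ], each = N))^2)
    lab <- ifelse(d1 <= d2, 1L, 2L)
  } else {
    lab <- kmeansPPLabels(X, 2L)
  }
  if (length(unique(lab)) < 2L) lab[1L] <- 3L - lab[1L]
  R <- labelsToResp(lab, 2L, floor = 0.05)
  wll <- -Inf
  comp <- NULL
  for (it in seq_len(maxIter)) {
    pis <- colSums(w * R) / sum(w)
    pis <- pmax(pis, 1e-8); pis <- pis / sum(pis)
    comp <- lapply(1:2, function(m) weightedBetaMLE(X, w * R[, m]))
    ll <- vapply(1:2, function(m)
      betaLogLikMatrix(X, comp[[m]]$u, comp[[m]]$v), numeric(N))
    ll <- sweep(ll, 2L, log(pis), "+")
    lse <- rowLogSumExp(ll)
    R <- exp(ll - lse)
    new_wll <- sum(w * lse)
    if (is.finite(wll) && abs(new_wll - wll) < tol * (abs(wll) + 1e-12)) {
      wll <- new_wll; break
    }
    wll <- new_wll
  }
  list(wll = wll, R = R, comp = comp, pis = pis)
}

#' Fit a recursive-partitioning beta mixture model
#'
#' Recursively splits the data into a binary tree of independent-beta
#' mixture components. At each node, 1- and 2-component models are fitted
#' with the node's responsibilities as observation weights; the split is
#' accepted iff the weighted BIC (-2 weighted log-likelihood + number of
#' free parameters x ln(sum of weights)) decreases. Leaves are the final
#' clusters; their path labels ("rL", "rRL", ...) order children so that
#' "L" is the child with the smaller weighted mean of the first feature.
#'
#' @param Y numeric N x K matrix with entries strictly in (0, 1).
#' @param seed integer seed (EM initializations).
#' @param maxDepth maximum tree depth (default 6).
#' @param minWeight minimum effective node size to attempt a split
#'   (default 4).
#' @return A \linkS4class{MixtureFit} with family "beta-recursive";
#'   `extras$pathLabels` holds the per-cluster split-path labels and
#'   `extras$tree` the per-node weighted-BIC bookkeeping. `elboTrace()` is
#'   empty for this family.
#' @export
fitRPBMM <- function(Y, seed = 1L, maxDepth = 6L, minWeight = 4) {
  Y <- as.matrix(Y)
  if (any(Y <= 0 | Y >= 1))
    stop("Y contains values at or beyond 0/1; clip into [1e-6, 1 - 1e-6] first")
  N <- nrow(Y); K <- ncol(Y)

  leaves <- list()
  tree <- list()
  recurse <- function(w, path, depth) {
    W <- sum(w)
    fit1 <- weightedBetaMLE(Y, w)
    wll1 <- sum(w * betaLogLikMatrix(Y, fit1$u, fit1$v))
    bic1 <- -2 * wll1 + (2 * K) * log(W)
    split <- FALSE
    if (depth < maxDepth && W >= minWeight) {
      em <- betaMixEM2(Y, w)
      bic2 <- -2 * em$wll + (4 * K + 1) * log(W)
      tree[[length(tree) + 1L]] <<- list(path = path, bic1 = bic1,
                                         bic2 = bic2, weight = W)
      if (bic2 < bic1) split <- TRUE
    } else {
      tree[[length(tree) + 1L]] <<- list(path = path, bic1 = bic1,
                                         bic2 = NA_real_, weight = W)
    }
    if (!split) {
      leaves[[length(leaves) + 1L]] <<-
        list(path = path, w = w, u = fit1$u, v = fit1$v)
      return(invisible(NULL))
    }
    ## order children: "L" has the smaller weighted mean of feature 1
    m1 <- vapply(1:2, function(m)
      sum(w * em$R[, m] * Y[, 1L]) / sum(w * em$R[, m]), numeric(1))
    ord <- order(m1)
    recurse(w * em$R[, ord[1L]], paste0(path, "L"), depth + 1L)
    recurse(w * em$R[, ord[2L]], paste0(path, "R"), depth + 1L)
  }
  withr::with_seed(as.integer(seed), recurse(rep(1, N), "r", 0L))

  Wmat <- vapply(leaves, function(l) l$w, numeric(N))
  if (is.null(dim(Wmat))) Wmat <- matrix(Wmat, N, 1L)
  R <- Wmat / rowSums(Wmat)
  new("MixtureFit", family = "beta-recursive",
      weights = colSums(R) / N,
      params = lapply(leaves, function(l) list(u = l$u, v = l$v)),
      responsibilities = R,
      labels = as.integer(apply(R, 1L, which.max)),
      Meffective = as.integer(ncol(R)),
      elbo = numeric(0),
      extras = list(pathLabels = vapply(leaves, `[[`, "", "path"),
                    tree = tree))
}
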