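## Seeded generators for every input the models consume: methylation-like
## grouped beta matrices (a normal group plus heterogeneous cancer
## subgroups), exact draws from the BG-NMF generative model, and directional
## mixtures on the unit hypersphere. Each generator is a pure function of
## its parameter record; regeneration from the recorded parameters is
## bitwise identical.

## Default emulation profile mirrors a 27k-array breast cohort: 136 samples
## of which 23 normals and 113 cancers split into three subgroups.
#' @noRd
defaultGroupSizes <- function() c(23L, 40L, 40L, 33L)

#' Simulate a grouped methylation-like beta-value matrix
#'
#' Generates a CpG-by-sample matrix of beta-values with planted group
#' structure. Non-differential CpGs share one beta law across all groups;
#' a fraction `dmFraction` of CpGs are differentially methylated, their
#' group mean shifted by a group-specific multiple of `delta` (alternating
#' direction so groups separate from each other, not only from the first
#' group). Per-entry draws are Beta(m * conc, (1 - m) * conc) with m the
#' group mean, so `concentration` controls within-group noise. Entries are
#' clipped into [1e-6, 1 - 1e-6].
#'
#' @param P number of CpGs.
#' @param T number of samples.
#' @param groupSizes integer vector summing to T; the first group plays the
#'   "normal" role in evaluation. Default: 23 normals plus cancer subgroups
#'   of 40, 40 and 33 (a 136-sample breast-cohort profile).
#' @param dmFraction fraction of CpGs that are differentially methylated.
#' @param delta base mean shift at DM CpGs; must keep means inside (0, 1).
#' @param concentration beta precision of each entry (default 30).
#' @param seed integer seed.
#' @return A list (the synthetic truth record) with elements `X`
#'   (\linkS4class{BetaValueMatrix} with class labels "normal"/"cancer"),
#'   `groupLabels` (integer per sample), `dmRows` (indices of DM CpGs),
#'   `trueMeanMatrix` and `params`.
#' @examples
#' sim <- simulateGroupMethylation(P = 100, T = 30,
#'                                 groupSizes = c(10, 10, 10), seed = 1)
#' table(sim$groupLabels)
#' @export
simulateGroupMethylation <- function(P = 1000L, T = 136L,
                                     groupSizes = defaultGroupSizes(),
                                     dmFraction = 0.2, delta = 0.3,
                                     concentration = 30, seed = 1L) {
  groupSizes <- as.integer(groupSizes)
  if (sum(groupSizes) != T)
    stop("groupSizes must sum to the sample count T")
  if (dmFraction < 0 || dmFraction >= 1)
    stop("dmFraction must lie in [0, 1)")
  G <- length(groupSizes)
  params <- list(P = P, T = T, groupSizes = groupSizes,
                 dmFraction = dmFraction, delta = delta,
                 concentration = concentration, seed = as.integer(seed))
  out <- withr::with_seed(as.integer(seed), {
    groupLabels <- rep(seq_len(G), groupSizes)
    nDM <- round(dmFraction * P)
    dmRows <- if (nDM > 0) sort(sample.int(P, nDM)) else integer(0)
    baseMean <- stats::runif(P, 0.15, 0.85)
    M <- matrix(baseMean, P, T)
    if (nDM > 0) {
      for (g in seq_len(G)[-1L]) {
        ## each group beyond the first owns its own DM CpG subset, shifted
        ## by delta toward the interval center so groups separate from one
        ## another (disjoint DM sets) while means stay inside (0, 1)
        rows <- dmRows[seq_along(dmRows) %% G == (g - 1L)]
        cols <- which(groupLabels == g)
        shift <- delta * ifelse(baseMean[rows] < 0.5, 1, -1)
        M[rows, cols] <- M[rows, cols] + shift
      }
    }
    if (any(M <= 0 | M >= 1))
      stop("delta pushes group means outside (0, 1); reduce delta")
    X <- matrix(stats::rbeta(P * T, M * concentration,
                             (1 - M) * concentration), P, T)
    list(X = clipUnitInterval(X), M = M, groupLabels = groupLabels,
         dmRows = dmRows)
  })
  dimnames(out$X) <- list(sprintf("cg%05d", seq_len(P)),
                          sprintf("s%03d", seq_len(T)))
  cls <- ifelse(out$groupLabels == 1L, "normal", "cancer")
  list(X = BetaValueMatrix(out$X, sampleClass = cls),
       groupLabels = out$groupLabels, dmRows = out$dmRows,
       trueMeanMatrix = out$M, params = params)
}

#' Simulate from the BG-NMF generative model
#'
#' Draws A (P x K), B (P x K) and H (K x T) from their gamma priors and each
#' X_pt from Beta(sum_k A_pk H_kt, sum_k B_pk H_kt). The returned
#' `trueMeanMatrix` is AH / (AH + BH) element-wise -- the quantity a fitted
#' factorization should reconstruct.
#'
#' @param P,T,K matrix sizes and inner dimension.
#' @param priors named list of gamma hyperparameters as in [fitBGNMF()].
#' @param groupH optional integer count of sample groups; when given, H is
#'   drawn with block structure (each group loads mainly on its own
#'   components) so samples form K recoverable clusters, and `groupLabels`
#'   records them.
#' @param seed integer seed.
#' @return List with `X` (\linkS4class{BetaValueMatrix}), `A`, `B`, `H`,
#'   `trueMeanMatrix`, optional `groupLabels`, and `params`.
#' @export
simulateBGNMFMatrix <- function(P = 200L, T = 60L, K = 3L,
                                priors = defaultBGNMFPriors(),
                                groupH = NULL, seed = 1L) {
  pr <- utils::modifyList(defaultBGNMFPriors(), as.list(priors))
  params <- list(P = P, T = T, K = K, priors = pr, groupH = groupH,
                 seed = as.integer(seed))
  out <- withr::with_seed(as.integer(seed), {
    A <- matrix(stats::rgamma(P * K, pr$mu0, pr$alpha0), P, K)
    B <- matrix(stats::rgamma(P * K, pr$nu0, pr$beta0), P, K)
    H <- matrix(stats::rgamma(K * T, pr$rho0, pr$zeta0), K, T)
    groupLabels <- NULL
    if (!is.null(groupH)) {
      groupLabels <- rep_len(seq_len(K), T)[order(stats::runif(T))]
      boost <- matrix(0.05, K, T)
      boost[cbind(groupLabels, seq_len(T))] <- 1
      H <- (H + 0.5) * boost * 3
    }
    a <- A %*% H; b <- B %*% H
    X <- matrix(stats::rbeta(P * T, a, b), P, T)
    list(X = clipUnitInterval(X), A = A, B = B, H = H,
         M = a / (a + b), groupLabels = groupLabels)
  })
  dimnames(out$X) <- list(sprintf("cg%05d", seq_len(P)),
                          sprintf("s%03d", seq_len(T)))
  list(X = BetaValueMatrix(out$X), A = out$A, B = out$B, H = out$H,
       trueMeanMatrix = out$M, groupLabels = out$groupLabels,
       params = params)
}

#' Simulate a directional mixture on the unit hypersphere
#'
#' Component axes are drawn at random but constrained to pairwise angles of
#' at least 60 degrees (resampled until satisfied), then samples are drawn
#' from the package's von Mises-Fisher or Watson samplers.
#'
#' @param family "vmf" or "watson".
#' @param M number of components.
#' @param K ambient dimension (>= 2).
#' @param kappas concentration(s), recycled to length M.
#' @param weights mixture weights (default uniform), must sum to 1.
#' @param n number of samples.
#' @param seed integer seed.
#' @return List with `X` (n x K unit row vectors), `groupLabels`, `axes`
#'   (M x K), and `params`.
#' @export
simulateDirectionalMixture <- function(family = c("vmf", "watson"),
                                       M = 3L, K = 3L, kappas = 40,
                                       weights = NULL, n = 300L,
                                       seed = 1L) {
  family <- match.arg(family)
  kappas <- rep_len(kappas, M)
  if (is.null(weights)) weights <- rep(1 / M, M)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (M > 2 * K)
    stop("too many components for the 60-degree separation constraint")
  params <- list(family = family, M = M, K = K, kappas = kappas,
                 weights = weights, n = n, seed = as.integer(seed))
  out <- withr::with_seed(as.integer(seed), {
    repeat {
      axes <- matrix(stats::rnorm(M * K), M, K)
      axes <- axes / sqrt(rowSums(axes^2))
      cosang <- abs(tcrossprod(axes))
      diag(cosang) <- 0
      if (max(cosang) <= cos(pi / 3) || M == 1L) break
    }
    lab <- sample.int(M, n, replace = TRUE, prob = weights)
    X <- matrix(NA_real_, n, K)
    for (m in seq_len(M)) {
      idx <- which(lab == m)
      if (!length(idx)) next
      X[idx, ] <- if (family == "vmf")
        rvmf(length(idx), axes[m, ], kappas[m])
      else rwatson(length(idx), axes[m, ], kappas[m])
    }
    list(X = X, lab = lab, axes = axes)
  })
  list(X = out$X, groupLabels = out$lab, axes = out$axes, params = params)
}
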