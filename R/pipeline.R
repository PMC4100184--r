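## The reduce -> cluster -> evaluate pipeline and Table-style scoring. Five
## method combinations are supported, each pairing a reduction with the
## clusterer whose support matches the reduced features: PCA scores are
## real-valued (Gaussian mixture), the BG-NMF pseudo-basis is bounded in
## (0,1) (beta mixtures), spectral features have unit norm (directional
## mixtures).

PIPELINE_PAIRS <- list(pca = "vbgmm",
                       bgnmf = c("vbbmm", "rpbmm"),
                       sc = c("vbvmm", "vbwmm"))

#' Score a clustering against known sample classes
#'
#' Maps each cluster to its majority truth class (ties broken toward the
#' larger class); a sample is misclustered iff its cluster's majority class
#' differs from its own. The error rate is 100 x misclustered / N. The two
#' directional counts follow the convention class1 = larger truth class:
#' in a normal-vs-cancer cohort they are the cancer-to-normal and
#' normal-to-cancer counts.
#'
#' @param labels per-sample cluster identifiers (any atomic type; RPBMM
#'   path labels welcome).
#' @param truth per-sample class labels with at least 2 classes.
#' @param method descriptive method string stored in the report.
#' @param Kused embedding dimension to record (NA if not applicable).
#' @param seed seed to record (NA if not applicable).
#' @return A \linkS4class{ClusterReport}.
#' @examples
#' truth <- rep(c("cancer", "normal"), c(113, 23))
#' labels <- truth; labels[1:4] <- "normal"   # 4 cancers misplaced
#' errorRate(evaluateClustering(labels, truth))
#' @export
evaluateClustering <- function(labels, truth, method = "custom",
                               Kused = NA_integer_, seed = NA_integer_) {
  if (length(labels) != length(truth))
    stop("labels and truth must have the same length")
  truth <- as.character(truth)
  if (length(unique(truth)) < 2L)
    stop("truth must contain at least 2 classes")
  N <- length(truth)
  conf <- table(cluster = as.character(labels), class = truth)
  classSizes <- sort(table(truth), decreasing = TRUE)
  classOrder <- names(sort(-classSizes))          # larger class first
  ## majority class per cluster; ties resolved toward the larger class
  majority <- apply(conf, 1L, function(row) {
    cand <- colnames(conf)[row == max(row)]
    cand[order(match(cand, classOrder))][1L]
  })
  predClass <- majority[as.character(labels)]
  wrong <- predClass != truth
  c1 <- classOrder[1L]; c2 <- classOrder[2L]
  m12 <- sum(wrong & truth == c1 & predClass == c2)
  m21 <- sum(wrong & truth == c2 & predClass == c1)
  confMat <- matrix(as.integer(conf), nrow(conf), ncol(conf),
                    dimnames = dimnames(conf))
  new("ClusterReport", method = method,
      nClusters = nrow(confMat),
      errorRate = 100 * sum(wrong) / N,
      miscl1to2 = as.integer(m12), miscl2to1 = as.integer(m21),
      classes = c(c1, c2), confusion = confMat,
      Kused = as.integer(Kused), seed = as.integer(seed))
}

#' Run a reduce-cluster-evaluate pipeline
#'
#' Executes top-variance CpG selection, dimension estimation (random-matrix
#' theory when `K = "rmt"`), one of three reductions and its compatible
#' clusterer, then scores the clustering against the sample classes.
#' Supported pairs: `pca + vbgmm` (real-valued scores), `bgnmf + vbbmm` or
#' `bgnmf + rpbmm` (bounded pseudo-basis; the factorization is fitted to
#' the transposed matrix so pseudo-basis rows index samples), `sc + vbvmm`
#' or `sc + vbwmm` (unit-norm spectral features). Any other pairing raises
#' a configuration error naming the constraint. Identical configuration and
#' seed give byte-identical reports.
#'
#' @param X \linkS4class{BetaValueMatrix} (CpGs x samples). Class labels
#'   for evaluation are taken from `colData(X)$class` unless `truth` is
#'   given.
#' @param reduction one of "pca", "bgnmf", "sc".
#' @param clusterer one of "vbgmm", "vbbmm", "rpbmm", "vbvmm", "vbwmm".
#' @param K integer embedding dimension, or "rmt" to estimate it.
#' @param nTopCpgs number of top-variance CpGs to keep first (NULL = all).
#' @param Minit initial component count for the variational clusterers
#'   (default 15 for vbbmm, 10 otherwise).
#' @param prune component-weight pruning threshold (default 0.01).
#' @param seed integer seed driving every stochastic step.
#' @param truth optional per-sample class labels overriding `colData`.
#' @param outDir optional directory; when given, writes `report.json`,
#'   `report_assignments.tsv` and `config.txt` there.
#' @return List with elements `report` (\linkS4class{ClusterReport}),
#'   `fit` (\linkS4class{MixtureFit}), `labels` (per-sample cluster labels,
#'   path labels for rpbmm), `features` (the reduced matrix handed to the
#'   clusterer), `K` and `config`.
#' @export
runPipeline <- function(X, reduction = c("pca", "bgnmf", "sc"),
                        clusterer = c("vbgmm", "vbbmm", "rpbmm",
                                      "vbvmm", "vbwmm"),
                        K = "rmt", nTopCpgs = NULL, Minit = NULL,
                        prune = 0.01, seed = 1L, truth = NULL,
                        outDir = NULL) {
  reduction <- match.arg(reduction)
  clusterer <- match.arg(clusterer)
  if (!clusterer %in% PIPELINE_PAIRS[[reduction]])
    stop(sprintf(
      paste0("incompatible pair %s + %s: %s features require one of {%s} ",
             "(vbbmm/rpbmm need bounded features from bgnmf; vbvmm/vbwmm ",
             "need unit features from sc; vbgmm takes pca scores)"),
      reduction, clusterer, reduction,
      paste(PIPELINE_PAIRS[[reduction]], collapse = ", ")))
  if (!is(X, "BetaValueMatrix")) X <- BetaValueMatrix(as.matrix(X))
  if (is.null(truth)) truth <- sampleClasses(X)
  if (is.null(truth))
    stop("no class labels: supply `truth` or colData(X)$class")
  if (is.null(Minit)) Minit <- if (clusterer == "vbbmm") 15L else 10L

  if (!is.null(nTopCpgs) && nTopCpgs < nrow(X))
    X <- selectTopVariance(X, nTopCpgs)
  mat <- betaValues(X)
  message(sprintf("[pipeline] input %d CpGs x %d samples",
                  nrow(mat), ncol(mat)))
  if (identical(K, "rmt")) {
    est <- estimateDimRMT(X)
    K <- est@K
    message(sprintf("[pipeline] RMT estimated K = %d (MP edge %.3f)",
                    K, est@threshold))
    if (K < 1L)
      stop("random-matrix theory found no signal dimensions; pass K explicitly")
  }
  K <- as.integer(K)

  seed <- as.integer(seed)
  if (reduction == "pca") {
    feat <- pcaReduce(X, K)                       # K x T
    fit <- fitVBGMM(feat, Minit = Minit, prune = prune, seed = seed)
  } else if (reduction == "bgnmf") {
    bg <- fitBGNMF(t(mat), K, seed = seed)        # samples x CpGs
    message(sprintf("[pipeline] BG-NMF: %d sweeps, ELBO %.2f",
                    bg@iterations, utils::tail(elboTrace(bg), 1L)))
    feat <- pseudoBasis(bg)@W                     # T x K, bounded
    fit <- if (clusterer == "vbbmm")
      fitVBBMM(feat, Minit = Minit, prune = prune, seed = seed)
    else fitRPBMM(feat, seed = seed)
  } else {
    feat <- spectralEmbed(X, K)                   # K x N unit columns
    fit <- if (clusterer == "vbvmm")
      fitVBVMM(t(feat), Minit = Minit, prune = prune, seed = seed)
    else fitVBWMM(t(feat), Minit = Minit, prune = prune, seed = seed)
  }
  message(sprintf("[pipeline] %s found %d cluster(s)",
                  clusterer, nComponents(fit)))

  labs <- clusterLabels(fit)
  labels <- if (fit@family == "beta-recursive")
    fit@extras$pathLabels[labs] else as.character(labs)
  names(labels) <- colnames(mat)

  method <- paste(reduction, clusterer, sep = "+")
  report <- evaluateClustering(labels, truth, method = method,
                               Kused = K, seed = seed)
  config <- list(reduction = reduction, clusterer = clusterer, K = K,
                 nTopCpgs = if (is.null(nTopCpgs)) nrow(mat) else nTopCpgs,
                 Minit = Minit, prune = prune, seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeReport(report, file.path(outDir, "report.json"),
                assignments = labels)
    writeLines(sprintf("%s: %s", names(config),
                       vapply(config, as.character, "")),
               file.path(outDir, "config.txt"))
  }
  list(report = report, fit = fit, labels = labels, features = feat,
       K = K, config = config)
}
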