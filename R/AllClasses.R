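#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' BetaValueMatrix: a bounded CpG-by-sample methylation matrix
#'
#' A thin subclass of \linkS4class{SummarizedExperiment} holding one assay
#' named \code{"beta"}: a CpG-by-sample matrix of DNA methylation
#' beta-values, each the estimated methylated fraction of cells at a CpG and
#' therefore bounded in [0, 1]. Rows are CpGs, columns are samples; both must
#' carry unique identifiers. Optional per-sample class labels (for
#' evaluation only, e.g. normal/cancer) live in \code{colData(x)$class}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots.
#' @seealso [BetaValueMatrix()], [betaValues()], [readBetaMatrix()]
#' @export
setClass("BetaValueMatrix", contains = "SummarizedExperiment")

setValidity("BetaValueMatrix", function(object) {
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is missing")
  b <- SummarizedExperiment::assay(object, "beta")
  if (!is.numeric(b)) return("assay 'beta' must be numeric")
  if (anyNA(b)) return("assay 'beta' contains missing values")
  if (any(b < 0 | b > 1)) return("beta-values must lie in [0, 1]")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("row (CpG) identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("column (sample) identifiers must be present and unique")
  TRUE
})

#' Construct a BetaValueMatrix
#'
#' Values exactly at 0 or 1 are clipped inward to \code{[1e-6, 1 - 1e-6]}
#' (the package-wide clipping constant), since every downstream model
#' evaluates log(x) and log(1-x).
#'
#' @param beta numeric CpG-by-sample matrix in [0, 1] with dimnames.
#' @param sampleClass optional character/factor of per-sample class labels
#'   (evaluation only), length ncol(beta).
#' @param clip logical; clip exact 0/1 inward (default TRUE). With
#'   \code{clip = FALSE} such values raise an error instructing the caller
#'   to clip.
#' @return A \linkS4class{BetaValueMatrix}.
#' @examples
#' m <- matrix(runif(12), 4, 3,
#'             dimnames = list(paste0("cg", 1:4), paste0("s", 1:3)))
#' BetaValueMatrix(m)
#' @export
BetaValueMatrix <- function(beta, sampleClass = NULL, clip = TRUE) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("cg%05d", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("sample%03d", seq_len(ncol(beta)))
  if (anyNA(beta)) stop("beta matrix contains missing values")
  if (any(beta < 0 | beta > 1)) {
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("beta-value out of [0, 1] at row '%s', column '%s'",
                 rownames(beta)[bad[1L]], colnames(beta)[bad[2L]]))
  }
  nclip <- sum(beta <= 0 | beta >= 1)
  if (nclip > 0) {
    if (!clip)
      stop(sprintf(
        "%d value(s) lie exactly at 0 or 1; clip them into [%g, %g] first",
        nclip, BETA_EPS, 1 - BETA_EPS))
    message(sprintf("clipped %d boundary value(s) into [%g, %g]",
                    nclip, BETA_EPS, 1 - BETA_EPS))
    beta <- clipUnitInterval(beta)
  }
  cd <- if (is.null(sampleClass)) {
    S4Vectors::DataFrame(row.names = colnames(beta))
  } else {
    if (length(sampleClass) != ncol(beta))
      stop("sampleClass must have one entry per sample")
    S4Vectors::DataFrame(class = as.character(sampleClass),
                         row.names = colnames(beta))
  }
  new("BetaValueMatrix",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta), colData = cd))
}

#' BGNMFFit: variational posterior of the beta-gamma matrix factorization
#'
#' Gamma variational posteriors (shape/rate parameterization, mean =
#' shape/rate) over the basis matrices A, B (P x K) and the shared
#' excitation matrix H (K x T) of the bounded-support factorization in which
#' each observed beta-value X_pt is beta-distributed with shape parameters
#' (AH)_pt and (BH)_pt. `elboTrace()` returns the evidence-lower-bound
#' surrogate tracked across sweeps; it is non-decreasing.
#'
#' @slot Ashape,Arate,Bshape,Brate P x K positive matrices.
#' @slot Hshape,Hrate K x T positive matrices.
#' @slot elbo numeric ELBO-surrogate trace, one value per sweep.
#' @slot K integer inner dimension.
#' @slot iterations integer sweeps run.
#' @slot converged logical; TRUE if the relative ELBO change fell below tol.
#' @seealso [fitBGNMF()], [reconstructMean()], [pseudoBasis()]
#' @export
setClass("BGNMFFit", representation(
  Ashape = "matrix", Arate = "matrix",
  Bshape = "matrix", Brate = "matrix",
  Hshape = "matrix", Hrate = "matrix",
  elbo = "numeric", K = "integer",
  iterations = "integer", converged = "logical"))

setValidity("BGNMFFit", function(object) {
  for (s in c("Ashape", "Arate", "Bshape", "Brate", "Hshape", "Hrate"))
    if (any(slot(object, s) <= 0))
      return(sprintf("all entries of %s must be positive", s))
  if (ncol(object@Ashape) != object@K || nrow(object@Hshape) != object@K)
    return("inner dimension mismatch")
  TRUE
})

#' PseudoBasis: bounded basis and excitation from a BG-NMF fit
#'
#' The pseudo-basis W = A / (A + B) (element-wise, at posterior means) keeps
#' every entry in (0, 1) -- the same bounded support as the data -- while the
#' excitation matrix H carries the positive loadings shared by the two shape
#' factorizations.
#'
#' @slot W P x K matrix with entries strictly in (0, 1).
#' @slot H K x T matrix with positive entries.
#' @export
setClass("PseudoBasis", representation(W = "matrix", H = "matrix"))

setValidity("PseudoBasis", function(object) {
  if (any(object@W <= 0 | object@W >= 1))
    return("pseudo-basis entries must lie strictly in (0, 1)")
  if (any(object@H <= 0)) return("excitation entries must be positive")
  if (ncol(object@W) != nrow(object@H)) return("inner dimension mismatch")
  TRUE
})

#' MixtureFit: a fitted mixture model with automatic complexity selection
#'
#' Common container for the five clustering back-ends (gaussian, beta,
#' beta-recursive, vmf, watson). Responsibilities are the posterior
#' component-membership probabilities (rows sum to 1); components whose
#' weight fell below the pruning threshold have been removed, so
#' `nComponents()` can be smaller than the initial component count. The
#' recursive-partitioning fit carries a weighted-BIC trace and split tree in
#' `extras` instead of an ELBO trace.
#'
#' @slot family one of "gaussian", "beta", "beta-recursive", "vmf", "watson".
#' @slot weights mixture weights over surviving components (sums to 1).
#' @slot params list of per-component posterior parameters (family-specific).
#' @slot responsibilities N x M row-stochastic matrix.
#' @slot labels integer argmax cluster per observation (1..M).
#' @slot Meffective integer number of surviving components.
#' @slot elbo numeric ELBO-surrogate trace (empty for "beta-recursive").
#' @slot extras list of family-specific extras (e.g. split tree, path labels).
#' @export
setClass("MixtureFit", representation(
  family = "character", weights = "numeric", params = "list",
  responsibilities = "matrix", labels = "integer",
  Meffective = "integer", elbo = "numeric", extras = "list"))

setValidity("MixtureFit", function(object) {
  if (!object@family %in% c("gaussian", "beta", "beta-recursive",
                            "vmf", "watson"))
    return("unknown mixture family")
  if (abs(sum(object@weights) - 1) > 1e-10)
    return("mixture weights must sum to 1")
  rs <- rowSums(object@responsibilities)
  if (any(abs(rs - 1) > 1e-10))
    return("responsibility rows must sum to 1")
  if (object@Meffective != length(object@weights))
    return("Meffective must match the number of surviving components")
  if (any(object@labels < 1L | object@labels > object@Meffective))
    return("labels out of range")
  TRUE
})

#' DimensionEstimate: random-matrix-theory signal dimension
#'
#' Number of correlation-matrix eigenvalues exceeding the Marchenko-Pastur
#' upper edge \eqn{(1 + \sqrt{T/P})^2}; eigenvalues above that edge are
#' inconsistent with pure noise and counted as signal dimensions.
#'
#' @slot K integer estimated dimension.
#' @slot eigenvalues numeric descending eigenvalues.
#' @slot threshold numeric Marchenko-Pastur upper edge used.
#' @seealso [estimateDimRMT()]
#' @export
setClass("DimensionEstimate", representation(
  K = "integer", eigenvalues = "numeric", threshold = "numeric"))

setValidity("DimensionEstimate", function(object) {
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be in descending order")
  if (object@K != sum(object@eigenvalues > object@threshold))
    return("K must equal the count of eigenvalues above the threshold")
  TRUE
})

#' ClusterReport: evaluation of a clustering against known classes
#'
#' Each cluster is mapped to its majority truth class; a sample is
#' misclustered iff its cluster's majority class differs from its own. The
#' error rate is 100 x (misclustered / N). For two-class truth the two
#' directional counts record class1-to-class2 and class2-to-class1
#' misclusterings, where class1 is the larger truth class (cancer, in the
#' normal-vs-cancer setting).
#'
#' @slot method string naming the reduce+cluster combination.
#' @slot nClusters integer number of clusters evaluated.
#' @slot errorRate percentage in [0, 100].
#' @slot miscl1to2,miscl2to1 integer directional misclustering counts.
#' @slot classes character(2): the (class1, class2) convention used.
#' @slot confusion cluster-by-class contingency table (counts).
#' @slot Kused integer embedding dimension used (NA if not applicable).
#' @slot seed integer seed recorded for reproducibility.
#' @seealso [evaluateClustering()], [runPipeline()]
#' @export
setClass("ClusterReport", representation(
  method = "character", nClusters = "integer", errorRate = "numeric",
  miscl1to2 = "integer", miscl2to1 = "integer", classes = "character",
  confusion = "matrix", Kused = "integer", seed = "integer"))

setValidity("ClusterReport", function(object) {
  if (object@errorRate < 0 || object@errorRate > 100)
    return("errorRate must be a percentage in [0, 100]")
  if (object@miscl1to2 < 0 || object@miscl2to1 < 0)
    return("directional counts must be nonnegative")
  TRUE
})
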