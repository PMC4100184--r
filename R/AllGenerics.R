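#' Extract the beta-value matrix
#' @param x a \linkS4class{BetaValueMatrix}.
#' @return The numeric CpG-by-sample matrix.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Per-sample class labels (or NULL)
#' @param x a \linkS4class{BetaValueMatrix}.
#' @return Character vector of class labels, or NULL when absent.
#' @export
setGeneric("sampleClasses", function(x) standardGeneric("sampleClasses"))

#' Posterior-mean reconstruction of a factorized beta matrix
#' @param object a \linkS4class{BGNMFFit}.
#' @return P x T matrix with entries strictly in (0, 1).
#' @export
setGeneric("reconstructMean",
           function(object) standardGeneric("reconstructMean"))

#' Bounded pseudo-basis of a BG-NMF fit
#' @param object a \linkS4class{BGNMFFit}.
#' @return A \linkS4class{PseudoBasis}.
#' @export
setGeneric("pseudoBasis", function(object) standardGeneric("pseudoBasis"))

#' ELBO-surrogate trace of a variational fit
#' @param object a \linkS4class{BGNMFFit} or \linkS4class{MixtureFit}.
#' @return Numeric vector, one value per sweep.
#' @export
setGeneric("elboTrace", function(object) standardGeneric("elboTrace"))

#' Cluster labels of a mixture fit
#' @param object a \linkS4class{MixtureFit}.
#' @return Integer vector of argmax component assignments.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' Responsibility matrix of a mixture fit
#' @param object a \linkS4class{MixtureFit}.
#' @return N x M row-stochastic matrix.
#' @export
setGeneric("responsibilities",
           function(object) standardGeneric("responsibilities"))

#' Mixture weights of the surviving components
#' @param object a \linkS4class{MixtureFit}.
#' @return Numeric simplex vector.
#' @export
setGeneric("mixtureWeights",
           function(object) standardGeneric("mixtureWeights"))

#' Number of surviving mixture components
#' @param object a \linkS4class{MixtureFit}.
#' @return Integer count after pruning.
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' Error rate of a cluster report
#' @param object a \linkS4class{ClusterReport}.
#' @return Percentage in [0, 100].
#' @export
setGeneric("errorRate", function(object) standardGeneric("errorRate"))

#' Directional misclustering counts
#' @param object a \linkS4class{ClusterReport}.
#' @return Named integer vector (class1->class2, class2->class1).
#' @export
setGeneric("misclusterCounts",
           function(object) standardGeneric("misclusterCounts"))
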