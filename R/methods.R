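#' @describeIn BetaValueMatrix beta-value matrix accessor
#' @param x a BetaValueMatrix
#' @export
setMethod("betaValues", "BetaValueMatrix", function(x)
  SummarizedExperiment::assay(x, "beta"))

#' @describeIn BetaValueMatrix per-sample class labels, or NULL
#' @export
setMethod("sampleClasses", "BetaValueMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("class" %in% colnames(cd)) as.character(cd$class) else NULL
})

#' @describeIn BGNMFFit ELBO-surrogate trace
#' @param object a BGNMFFit
#' @export
setMethod("elboTrace", "BGNMFFit", function(object) object@elbo)

#' @describeIn MixtureFit ELBO-surrogate trace (empty for "beta-recursive")
#' @param object a MixtureFit
#' @export
setMethod("elboTrace", "MixtureFit", function(object) object@elbo)

#' @describeIn MixtureFit argmax cluster assignments
#' @export
setMethod("clusterLabels", "MixtureFit", function(object) object@labels)

#' @describeIn MixtureFit row-stochastic responsibility matrix
#' @export
setMethod("responsibilities", "MixtureFit",
          function(object) object@responsibilities)

#' @describeIn MixtureFit surviving mixture weights
#' @export
setMethod("mixtureWeights", "MixtureFit", function(object) object@weights)

#' @describeIn MixtureFit surviving component count
#' @export
setMethod("nComponents", "MixtureFit", function(object) object@Meffective)

#' @describeIn ClusterReport error-rate accessor (percent)
#' @param object a ClusterReport
#' @export
setMethod("errorRate", "ClusterReport", function(object) object@errorRate)

#' @describeIn ClusterReport directional misclustering counts
#' @export
setMethod("misclusterCounts", "ClusterReport", function(object) {
  stats::setNames(c(object@miscl1to2, object@miscl2to1),
                  c(paste(object@classes[1L], object@classes[2L], sep = "->"),
                    paste(object@classes[2L], object@classes[1L], sep = "->")))
})

setMethod("show", "BGNMFFit", function(object) {
  cat(sprintf(
    "BGNMFFit: P=%d features x T=%d samples, inner dimension K=%d\n",
    nrow(object@Ashape), ncol(object@Hshape), object@K))
  cat(sprintf("  %d sweep(s), %s; final ELBO surrogate %.4f\n",
              object@iterations,
              if (object@converged) "converged" else "iteration cap reached",
              utils::tail(object@elbo, 1L)))
})

setMethod("show", "PseudoBasis", function(object) {
  cat(sprintf(
    "PseudoBasis: bounded basis W %d x %d in (0,1); excitation H %d x %d\n",
    nrow(object@W), ncol(object@W), nrow(object@H), ncol(object@H)))
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit (%s family): %d observation(s), %d component(s)\n",
              object@family, nrow(object@responsibilities),
              object@Meffective))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n")
})

setMethod("show", "DimensionEstimate", function(object) {
  cat(sprintf(
    "DimensionEstimate: K=%d eigenvalue(s) above Marchenko-Pastur edge %.4f\n",
    object@K, object@threshold))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport [%s]: %d cluster(s), error rate %.2f%%\n",
              object@method, object@nClusters, object@errorRate))
  cat(sprintf("  %s->%s: %d   %s->%s: %d\n",
              object@classes[1L], object@classes[2L], object@miscl1to2,
              object@classes[2L], object@classes[1L], object@miscl2to1))
})
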