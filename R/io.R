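## File I/O for the pipeline: delimited beta matrices in (header row of
## sample ids, first column of CpG ids), report JSON and assignment TSV out.

#' Read a beta-value matrix from a delimited text file
#'
#' Expects a header row of sample identifiers, a first column of CpG
#' identifiers, and a numeric body of beta-values in [0, 1]; the delimiter
#' (tab or comma) is sniffed from the header. Values exactly at 0 or 1 are
#' clipped into [1e-6, 1 - 1e-6] with a message reporting the count; values
#' outside [0, 1], missing cells and duplicate CpG ids are rejected with
#' the offending coordinates.
#'
#' @param path path to a TSV/CSV file.
#' @param labels optional path to a two-column (sample_id, class) TSV whose
#'   classes are attached as `colData(x)$class` for evaluation.
#' @return A \linkS4class{BetaValueMatrix}.
#' @export
readBetaMatrix <- function(path, labels = NULL) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate CpG id '%s'", ids[duplicated(ids)][1L]))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row '%s', column '%s'",
                 ids[bad[1L]], colnames(mat)[bad[2L]]))
  }
  cls <- NULL
  if (!is.null(labels)) {
    lab <- utils::read.table(labels, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    cls <- lab[[2L]][match(colnames(mat), lab[[1L]])]
    if (anyNA(cls)) stop("labels file is missing some sample ids")
  }
  BetaValueMatrix(mat, sampleClass = cls)
}

#' Write a cluster report and assignments to disk
#'
#' Serializes all \linkS4class{ClusterReport} fields to JSON (confusion
#' table keyed by cluster label, so recursive-partitioning path labels like
#' "rLLR" are preserved) and, when sample assignments are supplied, a
#' two-column (sample_id, cluster) TSV next to it.
#'
#' @param report a \linkS4class{ClusterReport}.
#' @param path output JSON path.
#' @param assignments optional named vector/factor of per-sample cluster
#'   labels written to `sub("\\.json$", "_assignments.tsv", path)`.
#' @return Invisibly, the JSON path.
#' @export
writeReport <- function(report, path, assignments = NULL) {
  conf <- report@confusion
  confList <- stats::setNames(
    lapply(seq_len(nrow(conf)), function(i) as.list(conf[i, ])),
    rownames(conf))
  obj <- list(method = report@method,
              n_clusters = report@nClusters,
              error_rate = report@errorRate,
              miscl_class1_to_class2 = report@miscl1to2,
              miscl_class2_to_class1 = report@miscl2to1,
              classes = as.list(report@classes),
              confusion = confList,
              K_used = report@Kused,
              seed = report@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(assignments)) {
    tsv <- sub("\\.json$", "_assignments.tsv", path)
    utils::write.table(
      data.frame(sample_id = names(assignments),
                 cluster = as.character(assignments)),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a written cluster report
#'
#' @param path JSON path written by [writeReport()].
#' @return A \linkS4class{ClusterReport}.
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- do.call(rbind, lapply(obj$confusion, unlist))
  storage.mode(conf) <- "integer"
  names(dimnames(conf)) <- c("cluster", "class")
  new("ClusterReport", method = obj$method,
      nClusters = as.integer(obj$n_clusters),
      errorRate = as.numeric(obj$error_rate),
      miscl1to2 = as.integer(obj$miscl_class1_to_class2),
      miscl2to1 = as.integer(obj$miscl_class2_to_class1),
      classes = as.character(unlist(obj$classes)),
      confusion = conf,
      Kused = as.integer(obj$K_used),
      seed = as.integer(obj$seed))
}

#' Write a beta matrix as TSV
#'
#' @param x \linkS4class{BetaValueMatrix} or numeric matrix.
#' @param path output path (tab-separated, header = sample ids, first
#'   column `cpg_id`).
#' @return Invisibly, `path`.
#' @export
writeBetaMatrix <- function(x, path) {
  mat <- if (is(x, "BetaValueMatrix")) betaValues(x) else as.matrix(x)
  df <- data.frame(cpg_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
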