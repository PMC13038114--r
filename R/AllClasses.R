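#' @import methods
#' @importFrom stats cor quantile rnorm runif sd phyper coef predict
#' @importFrom utils head read.delim write.table
#' @useDynLib netRL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Weighted gene-gene graph
#'
#' A symmetric, nonnegative weighted adjacency over a fixed gene universe.
#' Node degrees are the row sums of the weight matrix. This is the graph
#' object behind both the centrality-based gene importance measure and the
#' normalized-Laplacian penalty.
#'
#' @slot geneIds character vector of gene identifiers (column order of the
#'   weight matrix).
#' @slot weights symmetric nonnegative numeric matrix with zero diagonal.
#'
#' @seealso [adjacencyFromCoefficients()], [adjacencyFromCorrelation()],
#'   [normalizedLaplacian()]
#' @export
setClass("WeightedGeneGraph",
         slots = c(geneIds = "character", weights = "matrix"))

setValidity("WeightedGeneGraph", function(object) {
  W <- object@weights
  p <- length(object@geneIds)
  msgs <- character()
  if (!is.numeric(W)) msgs <- c(msgs, "weights must be numeric")
  if (nrow(W) != p || ncol(W) != p)
    msgs <- c(msgs, "weights dimension must match geneIds length")
  if (anyNA(W)) msgs <- c(msgs, "weights must not contain NA")
  else {
    if (any(W < 0)) msgs <- c(msgs, "weights must be nonnegative")
    if (any(diag(W) != 0)) msgs <- c(msgs, "diagonal must be zero")
    if (max(abs(W - t(W))) > 1e-10) msgs <- c(msgs, "weights must be symmetric")
  }
  if (anyDuplicated(object@geneIds)) msgs <- c(msgs, "geneIds must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Normalized graph Laplacian
#'
#' The symmetric normalized Laplacian of a [WeightedGeneGraph-class]:
#' unit diagonal on connected nodes, \eqn{-w_{ij}/\sqrt{d_i d_j}} on edges,
#' and identically zero rows/columns for isolated nodes. Its eigenvalues lie
#' in \eqn{[0, 2]}; the quadratic form \eqn{\beta' L \beta} penalizes
#' differences between degree-scaled coefficients of network neighbours.
#'
#' @slot geneIds gene identifiers.
#' @slot matrix the Laplacian matrix.
#' @slot degrees node degrees of the source graph.
#' @export
setClass("NormalizedLaplacian",
         slots = c(geneIds = "character", matrix = "matrix",
                   degrees = "numeric"))

#' Inferred gene regulatory network
#'
#' Directed weighted edges (regulator -> target) retained by an edge
#' significance criterion, together with the per-edge significance record
#' and run metadata (bootstrap size, candidate-set sizes, seeds, criterion).
#' Unselected candidate edges are absent from the edge table, not
#' zero-filled.
#'
#' @slot geneIds the gene universe the network was inferred over.
#' @slot edges data.frame with columns `regulator`, `target`, `weight`,
#'   `m`, `p_perm`, `p_hyper`, `ci_low`, `ci_high`, `selected`.
#' @slot metadata list of run parameters.
#' @export
setClass("GeneNetwork",
         slots = c(geneIds = "character", edges = "data.frame",
                   metadata = "list"))

.edgeColumns <- c("regulator", "target", "weight", "m", "p_perm", "p_hyper",
                  "ci_low", "ci_high", "selected")

setValidity("GeneNetwork", function(object) {
  msgs <- character()
  miss <- setdiff(.edgeColumns, names(object@edges))
  if (length(miss))
    msgs <- c(msgs, paste("edge table missing columns:",
                          paste(miss, collapse = ", ")))
  if (nrow(object@edges)) {
    if (any(object@edges$regulator == object@edges$target))
      msgs <- c(msgs, "self-edges are not allowed")
    if (!all(object@edges$regulator %in% object@geneIds) ||
        !all(object@edges$target %in% object@geneIds))
      msgs <- c(msgs, "edge endpoints must be in geneIds")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn WeightedGeneGraph-class gene identifiers.
#' @param object a netRL S4 object.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @export
setMethod("geneIds", "WeightedGeneGraph", function(object) object@geneIds)

#' @export
setMethod("geneIds", "NormalizedLaplacian", function(object) object@geneIds)

#' @export
setMethod("geneIds", "GeneNetwork", function(object) object@geneIds)

#' @describeIn WeightedGeneGraph-class the symmetric weight matrix.
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' @export
setMethod("adjacencyMatrix", "WeightedGeneGraph", function(object) {
  W <- object@weights
  dimnames(W) <- list(object@geneIds, object@geneIds)
  W
})

#' @describeIn WeightedGeneGraph-class node degrees (row sums of weights).
#' @export
setGeneric("nodeDegrees", function(object) standardGeneric("nodeDegrees"))

#' @export
setMethod("nodeDegrees", "WeightedGeneGraph", function(object) {
  d <- rowSums(object@weights)
  names(d) <- object@geneIds
  d
})

#' @export
setMethod("nodeDegrees", "NormalizedLaplacian", function(object) {
  d <- object@degrees
  names(d) <- object@geneIds
  d
})

#' @describeIn NormalizedLaplacian-class the Laplacian matrix.
#' @param object a `NormalizedLaplacian`.
#' @export
setGeneric("laplacianMatrix", function(object) standardGeneric("laplacianMatrix"))

#' @export
setMethod("laplacianMatrix", "NormalizedLaplacian", function(object) {
  L <- object@matrix
  dimnames(L) <- list(object@geneIds, object@geneIds)
  L
})

#' @describeIn GeneNetwork-class the directed edge table.
#' @param object a `GeneNetwork`.
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @export
setMethod("edgeTable", "GeneNetwork", function(object) object@edges)

#' @describeIn GeneNetwork-class run metadata list.
#' @export
setGeneric("networkMetadata", function(object) standardGeneric("networkMetadata"))

#' @export
setMethod("networkMetadata", "GeneNetwork", function(object) object@metadata)

setMethod("show", "WeightedGeneGraph", function(object) {
  W <- object@weights
  ne <- sum(W[upper.tri(W)] > 0)
  cat("WeightedGeneGraph with", length(object@geneIds), "genes and",
      ne, "weighted edges\n")
  cat("  mean degree:", format(mean(rowSums(W)), digits = 4), "\n")
})

setMethod("show", "NormalizedLaplacian", function(object) {
  cat("NormalizedLaplacian over", length(object@geneIds), "genes (",
      sum(object@degrees == 0), "isolated )\n")
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork:", nrow(object@edges), "selected edges over",
      length(object@geneIds), "genes\n")
  md <- object@metadata
  if (length(md)) {
    keys <- intersect(c("criterion", "omega", "p2Star", "alpha"), names(md))
    if (length(keys))
      cat("  ", paste(sprintf("%s=%s", keys, unlist(md[keys])),
                      collapse = ", "), "\n", sep = "")
  }
  if (nrow(object@edges)) {
    cat("  top edges by |weight|:\n")
    e <- object@edges[order(-abs(object@edges$weight)), , drop = FALSE]
    print(utils::head(e[, c("regulator", "target", "weight")], 5),
          row.names = FALSE)
  }
})

#' Construct a GeneNetwork from an edge table
#'
#' @param edges data.frame with the standard edge columns (missing
#'   significance columns are filled with `NA`).
#' @param geneIds gene universe; defaults to the genes present in `edges`.
#' @param metadata list of run parameters.
#' @return a [GeneNetwork-class] object.
#' @export
geneNetwork <- function(edges, geneIds = NULL, metadata = list()) {
  if (is.null(geneIds))
    geneIds <- sort(unique(c(edges$regulator, edges$target)))
  for (cn in .edgeColumns) {
    if (!cn %in% names(edges))
      edges[[cn]] <- rep(if (cn == "selected") TRUE else NA_real_,
                         nrow(edges))
  }
  edges <- edges[, .edgeColumns, drop = FALSE]
  rownames(edges) <- NULL
  new("GeneNetwork", geneIds = as.character(geneIds), edges = edges,
      metadata = metadata)
}
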