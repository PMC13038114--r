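#' Weighted adjacency from averaged regression coefficients
#'
#' Symmetrizes a square matrix of (bootstrap-averaged) regression
#' coefficients into a weighted gene-gene adjacency:
#' \eqn{w_{kj} = (|\hat\beta^*_{kj}| + |\hat\beta^*_{jk}|)/2}, with zero
#' diagonal. Row `k` is read as the coefficients of the model with gene `k`
#' as target, so the two directed coefficients between a gene pair are
#' averaged in magnitude.
#'
#' @param coefMatrix square numeric matrix of averaged coefficients; the
#'   diagonal is ignored. Row/column names, if any, become gene ids.
#' @param geneIds optional gene identifiers overriding dimnames.
#' @return a [WeightedGeneGraph-class].
#' @examples
#' B <- matrix(c(0, 2, -4, 0), 2, 2, byrow = TRUE)
#' adjacencyMatrix(adjacencyFromCoefficients(B))
#' @export
adjacencyFromCoefficients <- function(coefMatrix, geneIds = NULL) {
  coefMatrix <- as.matrix(coefMatrix)
  if (nrow(coefMatrix) != ncol(coefMatrix))
    stop("coefMatrix must be square, got ", nrow(coefMatrix), " x ",
         ncol(coefMatrix))
  if (anyNA(coefMatrix)) stop("coefMatrix contains NA")
  if (is.null(geneIds))
    geneIds <- if (!is.null(rownames(coefMatrix))) rownames(coefMatrix) else
      paste0("g", seq_len(nrow(coefMatrix)))
  W <- (abs(coefMatrix) + t(abs(coefMatrix))) / 2
  diag(W) <- 0
  dimnames(W) <- NULL
  new("WeightedGeneGraph", geneIds = as.character(geneIds), weights = W)
}

#' Weighted adjacency from absolute pairwise correlation
#'
#' The external-prior variant of the gene-gene adjacency: each weight is the
#' absolute Pearson correlation between two genes' expression profiles.
#' Absolute values keep the weights (and hence node degrees and the
#' Laplacian's square roots) nonnegative.
#'
#' @param X samples-by-genes numeric matrix with at least 2 rows.
#' @return a [WeightedGeneGraph-class].
#' @export
adjacencyFromCorrelation <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to compute correlations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(head(which(sds == 0), 5), collapse = ", "),
         "; correlation adjacency is undefined")
  W <- abs(stats::cor(X))
  diag(W) <- 0
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(X)))
  dimnames(W) <- NULL
  new("WeightedGeneGraph", geneIds = ids, weights = W)
}

#' Normalized Laplacian of a weighted gene graph
#'
#' \eqn{l_{ij} = 1} if \eqn{i = j} and \eqn{d_i \neq 0};
#' \eqn{-w_{ij}/\sqrt{d_i d_j}} for edges; 0 otherwise. Rows and columns of
#' isolated genes are entirely zero, so an empty graph yields the zero
#' matrix and the Laplacian penalty vanishes.
#'
#' @param g a [WeightedGeneGraph-class].
#' @return a [NormalizedLaplacian-class].
#' @export
normalizedLaplacian <- function(g) {
  stopifnot(is(g, "WeightedGeneGraph"))
  W <- g@weights
  d <- rowSums(W)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -W * tcrossprod(inv)
  diag(L) <- ifelse(d > 0, 1, 0)
  new("NormalizedLaplacian", geneIds = g@geneIds, matrix = L,
      degrees = as.numeric(d))
}

#' Binarize a weighted graph
#'
#' Edge indicator \eqn{a_{jk} = 1} iff \eqn{w_{jk} > } `threshold`. The
#' default threshold 0 keeps every strictly positive weight, which is how
#' the bootstrap-averaged coefficient adjacency is turned into the binary
#' adjacency used by the centrality measures.
#'
#' @param g a [WeightedGeneGraph-class].
#' @param threshold nonnegative weight cutoff (strict inequality).
#' @return binary integer adjacency matrix with gene-id dimnames.
#' @export
binarizeAdjacency <- function(g, threshold = 0) {
  stopifnot(is(g, "WeightedGeneGraph"))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0)
    stop("threshold must be a single nonnegative number")
  A <- (g@weights > threshold) * 1L
  diag(A) <- 0L
  dimnames(A) <- list(g@geneIds, g@geneIds)
  A
}

.checkBinaryAdjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (anyNA(A) || !all(A %in% c(0, 1))) stop("adjacency must be binary")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
  if (max(abs(A - t(A))) > 0) stop("adjacency must be symmetric")
  A
}

#' Hubness centrality
#'
#' Degree of each gene normalized by the maximum attainable degree in a
#' universe of `pStar` genes: \eqn{H_j = \sum_k a_{jk} / (p^*-1) \in [0,1]}.
#' A gene adjacent to all others has hubness 1.
#'
#' @param A symmetric binary adjacency with zero diagonal.
#' @param pStar universe size (defaults to `nrow(A)`); must be >= 2.
#' @return numeric vector of per-gene hubness scores.
#' @export
hubness <- function(A, pStar = nrow(A)) {
  A <- .checkBinaryAdjacency(A)
  if (pStar < 2) stop("pStar must be at least 2")
  H <- colSums(A) / (pStar - 1)
  names(H) <- colnames(A)
  H
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each gene,
#' normalized by the number of ordered pairs excluding the gene,
#' \eqn{(|V|-1)(|V|-2)}, so scores lie in \eqn{[0,1]}. Shortest paths are
#' hop-count paths on the symmetrized unweighted graph (Brandes counting of
#' all shortest paths); disconnected pairs contribute 0. For fewer than 3
#' nodes the score is defined as 0.
#'
#' @param A symmetric binary adjacency with zero diagonal.
#' @return numeric vector of per-gene betweenness scores in `[0, 1]`.
#' @export
betweenness <- function(A) {
  A <- .checkBinaryAdjacency(A)
  nV <- nrow(A)
  if (nV < 3) {
    B <- rep(0, nV)
    names(B) <- colnames(A)
    return(B)
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  # igraph counts unordered pairs; the ordered-pair total is twice that
  B <- 2 * igraph::betweenness(g, directed = FALSE, normalized = FALSE) /
    ((nV - 1) * (nV - 2))
  B <- as.numeric(B)
  names(B) <- colnames(A)
  B
}

#' Read a prior network
#'
#' Accepts either a 3-column undirected edge list (`gene_a`, `gene_b`,
#' `weight`) or a square weight matrix with a header row of gene ids (first
#' column holding row ids). Edge weights must be nonnegative; edges listed
#' in both directions must agree.
#'
#' @param path text file path.
#' @param geneIds optional gene universe; edge-list input is expanded to it.
#' @return a [WeightedGeneGraph-class].
#' @export
readPriorNetwork <- function(path, geneIds = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  if (ncol(tab) == 3 && !all(vapply(tab, is.numeric, logical(1)))) {
    ga <- as.character(tab[[1]]); gb <- as.character(tab[[2]])
    wt <- as.numeric(tab[[3]])
    if (anyNA(wt)) stop("non-numeric weights in edge list")
    if (any(wt < 0)) stop("prior network weights must be nonnegative")
    ids <- if (is.null(geneIds)) sort(unique(c(ga, gb))) else geneIds
    if (!all(c(ga, gb) %in% ids))
      stop("edge list contains genes outside the supplied gene universe")
    W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ga)) {
      if (ga[i] == gb[i]) next
      W[ga[i], gb[i]] <- wt[i]
      W[gb[i], ga[i]] <- wt[i]
    }
    dimnames(W) <- NULL
    return(new("WeightedGeneGraph", geneIds = as.character(ids), weights = W))
  }
  ids <- as.character(tab[[1]])
  M <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(M)) stop("matrix input must be numeric")
  if (nrow(M) != ncol(M)) stop("matrix input must be square")
  W <- (M + t(M)) / 2
  diag(W) <- 0
  new("WeightedGeneGraph", geneIds = ids, weights = unname(W))
}

#' Write a prior network as an undirected edge list
#'
#' @param g a [WeightedGeneGraph-class].
#' @param path output path; writes columns `gene_a`, `gene_b`, `weight`
#'   for every strictly positive weight (upper triangle).
#' @return `path`, invisibly.
#' @export
writePriorNetwork <- function(g, path) {
  stopifnot(is(g, "WeightedGeneGraph"))
  W <- g@weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  tab <- data.frame(gene_a = g@geneIds[idx[, 1]],
                    gene_b = g@geneIds[idx[, 2]],
                    weight = format(W[idx], digits = 12))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
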