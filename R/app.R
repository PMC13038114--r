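# File formats, the two-condition differential-network workflow, and the
# command-line entry point.

.detectSep <- function(path) {
  line <- readLines(path, n = 1)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read an expression matrix
#'
#' Delimited text (tab/comma/whitespace auto-detected) with a header of
#' identifiers; a non-numeric first column is taken as row identifiers.
#' Missing values and non-numeric cells are rejected with the offending
#' row/column named.
#'
#' @param path input file.
#' @param orientation `"samples-by-genes"` (default) or
#'   `"genes-by-samples"` (input is transposed).
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
readExpression <- function(path,
                           orientation = c("samples-by-genes",
                                           "genes-by-samples")) {
  orientation <- match.arg(orientation)
  sep <- .detectSep(path)
  tab <- utils::read.delim(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  if (ncol(tab) >= 1 && !is.numeric(tab[[1]])) {
    rn <- as.character(tab[[1]])
    nm <- names(tab)[-1]
    tab <- tab[, -1, drop = FALSE]
    names(tab) <- nm # data.frame subsetting repairs duplicated names
  } else {
    rn <- paste0(if (orientation == "samples-by-genes") "s" else "g",
                 seq_len(nrow(tab)))
  }
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      badRow <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1]
      stop("non-numeric value in column '", names(tab)[j], "', row ",
           if (is.na(badRow)) "?" else rn[badRow])
    }
    if (anyNA(tab[[j]]))
      stop("missing value in column '", names(tab)[j], "', row ",
           rn[which(is.na(tab[[j]]))[1]])
  }
  M <- as.matrix(tab)
  rownames(M) <- rn
  if (anyDuplicated(colnames(M)))
    stop("duplicate identifiers: ",
         paste(unique(colnames(M)[duplicated(colnames(M))]), collapse = ", "))
  if (orientation == "genes-by-samples") M <- t(M)
  if (anyDuplicated(colnames(M)))
    stop("duplicate gene identifiers after transposition")
  M
}

#' Write an expression matrix
#'
#' Tab-delimited, samples in rows, gene ids as header, sample ids in the
#' first column; values at 12 significant digits so write/read round-trips
#' are lossless at that precision.
#'
#' @param X numeric samples-by-genes matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(X, path) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  tab <- data.frame(sample = rownames(X),
                    apply(X, 2, format, digits = 12, trim = TRUE),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.configHeader <- function(metadata) {
  keep <- metadata[!vapply(metadata, is.null, logical(1))]
  keep <- keep[vapply(keep, function(x) is.atomic(x) && length(x) <= 10,
                      logical(1))]
  vapply(names(keep), function(k)
    sprintf("# %s: %s", k, paste(keep[[k]], collapse = ",")), character(1))
}

#' Write a gene network as a TSV edge list
#'
#' Columns `regulator`, `target`, `weight`, `m`, `p_perm`, `p_hyper`,
#' `ci_low`, `ci_high`, `selected`; the resolved run configuration is
#' emitted as leading `#` comment lines.
#'
#' @param net a [GeneNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "GeneNetwork"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.configHeader(networkMetadata(net)), con)
  e <- edgeTable(net)
  num <- vapply(e, is.numeric, logical(1)) & names(e) != "m"
  e[num] <- lapply(e[num], function(x) format(x, digits = 12, trim = TRUE))
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene network edge list
#'
#' @param path a TSV written by [writeEdgeList()] (leading `#` comment
#'   lines ignored).
#' @param geneIds optional gene universe.
#' @return a [GeneNetwork-class].
#' @export
readEdgeList <- function(path, geneIds = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("regulator", "target", "weight") %in% names(tab)))
    stop("edge list must have regulator, target and weight columns")
  if ("selected" %in% names(tab)) tab$selected <- as.logical(tab$selected)
  geneNetwork(tab, geneIds = geneIds)
}

#' Export a network in SIF format
#'
#' One line per edge: `regulator activates|represses target`, by the sign
#' of the edge weight.
#'
#' @param net a [GeneNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSif <- function(net, path) {
  stopifnot(is(net, "GeneNetwork"))
  e <- edgeTable(net)
  rel <- ifelse(e$weight >= 0, "activates", "represses")
  writeLines(paste(e$regulator, rel, e$target, sep = "\t"), path)
  invisible(path)
}

#' Keep the strongest fraction of edges
#'
#' Retains the `ceiling(fraction * E)` edges of largest absolute weight
#' (the display filter for large networks; the conventional default is the
#' top 0.1%). Edges tied with the cutoff weight are all kept.
#'
#' @param net a [GeneNetwork-class].
#' @param fraction fraction of edges to keep, in (0, 1].
#' @return a [GeneNetwork-class] with the filtered edge table.
#' @export
topFractionEdges <- function(net, fraction = 0.001) {
  stopifnot(is(net, "GeneNetwork"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  e <- edgeTable(net)
  if (nrow(e) == 0) return(net)
  k <- ceiling(fraction * nrow(e))
  thr <- sort(abs(e$weight), decreasing = TRUE)[k]
  keep <- abs(e$weight) >= thr
  geneNetwork(e[keep, , drop = FALSE], geneIds = geneIds(net),
              metadata = c(networkMetadata(net), list(topFraction = fraction)))
}

#' Hub genes of a network
#'
#' Genes ranked by total degree (in + out) over the selected edges; ties
#' break lexicographically by gene id.
#'
#' @param net a [GeneNetwork-class].
#' @param k number of genes to return.
#' @return data.frame with `gene` and `degree`, strongest hubs first.
#' @export
hubGenes <- function(net, k = 10) {
  stopifnot(is(net, "GeneNetwork"))
  if (k < 1) stop("k must be at least 1")
  e <- edgeTable(net)
  if (nrow(e) == 0)
    return(data.frame(gene = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  deg <- table(c(e$regulator, e$target))
  tab <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, k)
}

#' Differential network comparison
#'
#' Keys each network's selected edges by (regulator, target) and reports
#' the common edges, the condition-specific edges, per-network totals, and
#' the hub genes of each network.
#'
#' @param netA,netB two [GeneNetwork-class] objects over a shared gene
#'   universe (disjoint universes give a warning and proceed on the union).
#' @param hubK hub-table depth per network.
#' @return a `diffNetReport` list: `common`, `aSpecific`, `bSpecific`
#'   edge tables, `totals`, and `hubs` (gene, degree, network).
#' @export
differentialNetwork <- function(netA, netB, hubK = 10) {
  stopifnot(is(netA, "GeneNetwork"), is(netB, "GeneNetwork"))
  if (length(intersect(geneIds(netA), geneIds(netB))) == 0)
    warning("networks have disjoint gene universes; proceeding on the union")
  ea <- edgeTable(netA); eb <- edgeTable(netB)
  keyA <- paste(ea$regulator, ea$target, sep = "\r")
  keyB <- paste(eb$regulator, eb$target, sep = "\r")
  common <- ea[keyA %in% keyB, , drop = FALSE]
  aSpec <- ea[!keyA %in% keyB, , drop = FALSE]
  bSpec <- eb[!keyB %in% keyA, , drop = FALSE]
  hubs <- rbind(
    if (nrow(ea)) cbind(hubGenes(netA, hubK), network = "A"),
    if (nrow(eb)) cbind(hubGenes(netB, hubK), network = "B"))
  structure(list(common = common, aSpecific = aSpec, bSpecific = bSpec,
                 totals = c(A = nrow(ea), B = nrow(eb),
                            common = nrow(common)),
                 hubs = hubs),
            class = "diffNetReport")
}

#' @export
print.diffNetReport <- function(x, ...) {
  cat(sprintf(
    "Differential network report: %d edges in A, %d in B, %d common (%d A-specific, %d B-specific)\n",
    x$totals["A"], x$totals["B"], x$totals["common"],
    nrow(x$aSpecific), nrow(x$bSpecific)))
  invisible(x)
}

# ---------------------------------------------------------------- CLI ----

.cliUsage <- function() {
  paste(
    "usage: netrl <subcommand> [options]",
    "subcommands:",
    "  infer      infer a gene regulatory network from an expression matrix",
    "  simulate   generate a benchmark dataset",
    "  benchmark  run the Monte Carlo method comparison",
    "  diffnet    compare two inferred networks",
    sep = "\n")
}

.cliLog <- function(verbose, ...) if (verbose) message("[netrl] ", ...)

.cliConfigFromOpts <- function(opt) {
  cfg <- netrlConfig(
    omega = opt$omega, piReps = opt$pi, alpha = opt$alpha,
    criterion = opt$criterion, adjacency = opt$adjacency,
    aggregation = opt$aggregation)
  for (key in c("p1_star", "p2_star")) {
    val <- opt[[key]]
    if (!is.null(val) && !identical(val, "half")) {
      slot <- if (key == "p1_star") "p1Star" else "p2Star"
      cfg[[slot]] <- if (identical(val, "all")) NA_integer_ else
        as.integer(val)
    }
  }
  cfg
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/netrl.R` script; see the script or
#' `cliMain(character())` for usage. Options may also be supplied via a
#' YAML config file (`--config`), with command-line flags taking
#' precedence. Returns (invisibly) the process exit status: 0 on success,
#' 2 on usage errors, 1 on runtime failure; partially written outputs are
#' removed on failure.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
    message(.cliUsage())
    return(invisible(if (length(args) == 0) 2L else 0L))
  }
  sub <- args[1]
  rest <- args[-1]
  if (!sub %in% c("infer", "simulate", "benchmark", "diffnet")) {
    message("unknown subcommand '", sub, "'\n", .cliUsage())
    return(invisible(2L))
  }
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the 'optparse' package is required for the CLI")
    return(invisible(1L))
  }
  outputs <- character()
  status <- tryCatch({
    switch(sub,
           infer = .cliInfer(rest, function(p) outputs <<- c(outputs, p)),
           simulate = .cliSimulate(rest, function(p) outputs <<- c(outputs, p)),
           benchmark = .cliBenchmark(rest, function(p) outputs <<- c(outputs, p)),
           diffnet = .cliDiffnet(rest, function(p) outputs <<- c(outputs, p)))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    unlink(outputs)
    1L
  })
  invisible(status)
}

.cliCommonOptions <- function() {
  list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML file of option defaults"),
    optparse::make_option("--verbose", action = "store_true",
                          default = FALSE))
}

.cliParse <- function(optionList, args) {
  parser <- optparse::OptionParser(option_list = optionList)
  opt <- optparse::parse_args(parser, args = args)
  if (!is.null(opt$config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for --config")
    cfg <- yaml::read_yaml(opt$config)
    given <- sub("^--", "", grep("^--", args, value = TRUE))
    given <- sub("=.*", "", given)
    for (k in names(cfg))
      if (!gsub("_", "-", k) %in% given && !k %in% given)
        opt[[gsub("-", "_", k)]] <- cfg[[k]]
  }
  opt
}

.cliLogConfig <- function(opt) {
  keep <- opt[!vapply(opt, is.null, logical(1))]
  keep <- keep[names(keep) != "help"]
  .cliLog(TRUE, "resolved config: ",
          paste(sprintf("%s=%s", names(keep),
                        vapply(keep, function(x) paste(x, collapse = ","),
                               character(1))), collapse = " "))
  .cliLog(TRUE, "R ", getRversion(), ", netRL ",
          as.character(utils::packageVersion("netRL")))
}

.cliInfer <- function(args, registerOutput) {
  opts <- c(list(
    optparse::make_option("--expression", type = "character"),
    optparse::make_option("--orientation", type = "character",
                          default = "samples-by-genes"),
    optparse::make_option("--output", type = "character"),
    optparse::make_option("--targets", type = "character", default = "all"),
    optparse::make_option("--omega", type = "integer", default = 200L),
    optparse::make_option("--p1-star", type = "character", default = "half",
                          dest = "p1_star"),
    optparse::make_option("--p2-star", type = "character", default = "half",
                          dest = "p2_star"),
    optparse::make_option("--pi", type = "integer", default = 100L),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--criterion", type = "character",
                          default = "perm"),
    optparse::make_option("--adjacency", type = "character",
                          default = "beta"),
    optparse::make_option("--aggregation", type = "character",
                          default = "mean"),
    optparse::make_option("--groups", type = "character", default = NULL,
                          help = "2-column sample annotation TSV"),
    optparse::make_option("--group", type = "character", default = NULL),
    optparse::make_option("--sif", type = "character", default = NULL)),
    .cliCommonOptions())
  opt <- .cliParse(opts, args)
  if (is.null(opt$expression) || is.null(opt$output))
    stop("--expression and --output are required")
  if (opt$verbose) .cliLogConfig(opt)
  X <- readExpression(opt$expression, opt$orientation)
  cfg <- .cliConfigFromOpts(opt)
  for (slot in c("p1Star", "p2Star"))
    if (identical(cfg[[slot]], NA_integer_)) cfg[[slot]] <- ncol(X) - 1L
  targets <- if (identical(opt$targets, "all")) NULL else
    strsplit(opt$targets, ",")[[1]]
  groups <- NULL
  if (!is.null(opt$groups)) {
    g <- utils::read.delim(opt$groups, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    groups <- g[[2]][match(rownames(X), g[[1]])]
    if (anyNA(groups)) stop("group annotation missing for some samples")
  }
  net <- inferNetwork(X, targets = targets, config = cfg, seed = opt$seed,
                      groups = groups, group = opt$group)
  registerOutput(opt$output)
  writeEdgeList(net, opt$output)
  if (!is.null(opt$sif)) {
    registerOutput(opt$sif)
    writeSif(net, opt$sif)
  }
  .cliLog(opt$verbose, "wrote ", nrow(edgeTable(net)), " edges to ",
          opt$output)
  0L
}

.cliSimulate <- function(args, registerOutput) {
  opts <- c(list(
    optparse::make_option("--scenario", type = "integer", default = 1L),
    optparse::make_option("--situation", type = "integer", default = 1L),
    optparse::make_option("--u", type = "integer", default = 10L),
    optparse::make_option("--v", type = "integer", default = 10L),
    optparse::make_option("--sigma", type = "double", default = 1),
    optparse::make_option("--n", type = "integer", default = 60L),
    optparse::make_option("--output", type = "character")),
    .cliCommonOptions())
  opt <- .cliParse(opts, args)
  if (is.null(opt$output)) stop("--output prefix is required")
  if (opt$verbose) .cliLogConfig(opt)
  spec <- scenarioSpec(opt$scenario, opt$situation, opt$u, opt$v,
                       opt$sigma, opt$n)
  dset <- simulateDataset(spec, seed = opt$seed)
  paths <- paste0(opt$output, c("_train.tsv", "_test.tsv", "_beta.tsv"))
  for (p in paths) registerOutput(p)
  writeExpression(cbind(dset$Xtrain, target = dset$ytrain), paths[1])
  writeExpression(cbind(dset$Xtest, target = dset$ytest), paths[2])
  utils::write.table(
    data.frame(gene = colnames(dset$Xtrain), beta = dset$betaTrue),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  .cliLog(opt$verbose, "wrote ", paste(paths, collapse = ", "))
  0L
}

.cliBenchmark <- function(args, registerOutput) {
  opts <- c(list(
    optparse::make_option("--methods", type = "character",
                          default = "lasso,elastic-net"),
    optparse::make_option("--scenario", type = "integer", default = 1L),
    optparse::make_option("--situation", type = "integer", default = 1L),
    optparse::make_option("--u", type = "integer", default = 10L),
    optparse::make_option("--v", type = "integer", default = 10L),
    optparse::make_option("--sigma", type = "double", default = 1),
    optparse::make_option("--n", type = "integer", default = 60L),
    optparse::make_option("--n-datasets", type = "integer", default = 50L,
                          dest = "n_datasets"),
    optparse::make_option("--omega", type = "integer", default = 200L),
    optparse::make_option("--pi", type = "integer", default = 100L),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--criterion", type = "character",
                          default = "perm"),
    optparse::make_option("--adjacency", type = "character",
                          default = "beta"),
    optparse::make_option("--aggregation", type = "character",
                          default = "mean"),
    optparse::make_option("--output", type = "character")),
    .cliCommonOptions())
  opt <- .cliParse(opts, args)
  if (is.null(opt$output)) stop("--output is required")
  if (opt$verbose) .cliLogConfig(opt)
  spec <- scenarioSpec(opt$scenario, opt$situation, opt$u, opt$v,
                       opt$sigma, opt$n)
  cfg <- .cliConfigFromOpts(opt)
  res <- runBenchmark(strsplit(opt$methods, ",")[[1]], spec,
                      nDatasets = opt$n_datasets, seed = opt$seed,
                      config = cfg)
  registerOutput(opt$output)
  con <- file(opt$output, "w")
  writeLines(.configHeader(opt[!names(opt) %in% c("help", "config")]), con)
  utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  .cliLog(opt$verbose, "wrote ", nrow(res), " benchmark rows to ",
          opt$output)
  0L
}

.cliDiffnet <- function(args, registerOutput) {
  opts <- c(list(
    optparse::make_option("--a", type = "character"),
    optparse::make_option("--b", type = "character"),
    optparse::make_option("--output", type = "character"),
    optparse::make_option("--hub-k", type = "integer", default = 10L,
                          dest = "hub_k")),
    .cliCommonOptions())
  opt <- .cliParse(opts, args)
  if (is.null(opt$a) || is.null(opt$b) || is.null(opt$output))
    stop("--a, --b and --output are required")
  if (opt$verbose) .cliLogConfig(opt)
  rep <- differentialNetwork(readEdgeList(opt$a), readEdgeList(opt$b),
                             hubK = opt$hub_k)
  registerOutput(opt$output)
  con <- file(opt$output, "w")
  writeLines(c(.configHeader(opt[!names(opt) %in% c("help", "config")]),
               sprintf("# totals: A=%d B=%d common=%d", rep$totals["A"],
                       rep$totals["B"], rep$totals["common"])), con)
  lab <- function(df, set) if (nrow(df)) cbind(set = set, df) else NULL
  out <- rbind(lab(rep$common, "common"), lab(rep$aSpecific, "A-specific"),
               lab(rep$bSpecific, "B-specific"))
  if (is.null(out))
    out <- data.frame(set = character(), regulator = character(),
                      target = character())
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  0L
}
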