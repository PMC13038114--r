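# The three-stage netRL pipeline: centrality-weighted gene importance,
# network-constrained bootstrap ensemble estimation, and edge significance.

#' netRL run configuration
#'
#' Collects every tunable of the pipeline. Defaults follow the method's
#' reference settings: 200 bootstrap replicates, 100 permutations,
#' significance level 0.05, candidate-set sizes of half the regulator pool,
#' and the Laplacian penalty grid \{0, 0.01, 0.1, 1, 10\}.
#'
#' @param omega number of bootstrap replicates per stage.
#' @param p1Star,p2Star stage-1/stage-2 candidate-set sizes; `NULL` means
#'   half the number of available regulators (rounded up).
#' @param piReps permutation replicates for the permutation edge test.
#' @param alpha significance level for edge selection.
#' @param criterion edge selection criterion: permutation test (`"perm"`),
#'   hypergeometric calibration (`"hyper"`), percentile bootstrap interval
#'   (`"ci"`), or `"none"` (keep every nonzero averaged weight).
#' @param adjacency source of the gene-gene graph behind the centralities
#'   and the Laplacian: bootstrap-averaged coefficients (`"beta"`),
#'   absolute correlation (`"corr"`), or a user-supplied `prior`.
#' @param aggregation `"mean"` (default) or `"median"` aggregation of the
#'   stage-2 replicate coefficients into edge weights.
#' @param lambda2 Laplacian penalty grid.
#' @param nlambda,minRatio shape of the per-fit lambda1 path (log-spaced
#'   from \eqn{\lambda_{\max}} down to `minRatio` times it).
#' @param floorFrac floor added to zero importances so that sampling
#'   `p2Star` genes without replacement stays feasible, as a fraction of
#'   the largest importance; 0 disables the floor.
#' @param useCentrality if `FALSE` the importance measure is the plain
#'   absolute averaged bootstrap coefficient (the ordinary Random Lasso).
#' @param bootstrapSize bootstrap sample size; `NULL` uses all rows. In
#'   two-group analyses set this to the smaller group size (balanced
#'   bootstrap).
#' @param prior optional [WeightedGeneGraph-class] used when
#'   `adjacency = "prior"`.
#' @param sigma2 optional fixed noise variance for the BIC; `NULL`
#'   estimates it once per dataset via [estimateNoiseVariance()].
#' @param sigma2Perm noise variance used for the permuted reruns of the
#'   permutation test: `"per-column"` (default) re-estimates it from each
#'   permuted response so a permuted rerun is treated exactly like an
#'   observed dataset; `"same"` reuses the observed estimate.
#' @param ridgePenalty ridge penalty for the noise-variance plug-in
#'   (`NULL`: calibrated to half-rank effective df).
#' @param tol,maxit coordinate-descent control (convergence on max
#'   coefficient change; the BIC winner of each grid scan is solved at
#'   `tol`).
#' @param pathTol coarser tolerance used while scanning the penalty path;
#'   only the selected model is polished at `tol`.
#' @return a `netrlConfig` list.
#' @export
netrlConfig <- function(omega = 200, p1Star = NULL, p2Star = NULL,
                        piReps = 100, alpha = 0.05,
                        criterion = c("perm", "hyper", "ci", "none"),
                        adjacency = c("beta", "corr", "prior"),
                        aggregation = c("mean", "median"),
                        lambda2 = c(0, 0.01, 0.1, 1, 10),
                        nlambda = 50, minRatio = 0.001, floorFrac = 1e-6,
                        useCentrality = TRUE, bootstrapSize = NULL,
                        prior = NULL, sigma2 = NULL,
                        sigma2Perm = c("per-column", "same"),
                        ridgePenalty = NULL,
                        tol = 1e-7, maxit = 1e5, pathTol = 1e-4) {
  sigma2Perm <- match.arg(sigma2Perm)
  criterion <- match.arg(criterion)
  adjacency <- match.arg(adjacency)
  aggregation <- match.arg(aggregation)
  if (omega < 1) stop("omega must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (criterion == "perm" && piReps < 1) stop("piReps must be at least 1")
  if (any(lambda2 < 0)) stop("lambda2 values must be nonnegative")
  if (adjacency == "prior" && is.null(prior))
    stop("adjacency = 'prior' requires a prior WeightedGeneGraph")
  structure(list(omega = as.integer(omega), p1Star = p1Star,
                 p2Star = p2Star, piReps = as.integer(piReps), alpha = alpha,
                 criterion = criterion, adjacency = adjacency,
                 aggregation = aggregation, lambda2 = lambda2,
                 nlambda = as.integer(nlambda), minRatio = minRatio,
                 floorFrac = floorFrac, useCentrality = useCentrality,
                 bootstrapSize = bootstrapSize, prior = prior,
                 sigma2 = sigma2, sigma2Perm = sigma2Perm,
                 ridgePenalty = ridgePenalty,
                 tol = tol, maxit = as.integer(maxit), pathTol = pathTol),
            class = "netrlConfig")
}

# run expr under a local RNG seeded with `seed`, restoring the global state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# stable 31-adic hash of a gene id, for order-invariant per-target seeds
.hashId <- function(id) {
  h <- 0
  for (v in utf8ToInt(as.character(id))) h <- (h * 31 + v) %% 2147483647
  h
}

.targetSeed <- function(seed, id) {
  (as.numeric(seed) %% 65536 * 32749 + .hashId(id)) %% 2147483647
}

# split target spec into response + regulator design
.resolveTarget <- function(X, target) {
  X <- as.matrix(X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(X)))
  colnames(X) <- ids
  if (length(target) == 1 && (is.character(target) || target %in% seq_len(ncol(X)))) {
    j <- if (is.character(target)) match(target, ids) else as.integer(target)
    if (is.na(j) || j < 1 || j > ncol(X))
      stop("target gene '", target, "' not found in X")
    list(y = X[, j], Xreg = X[, -j, drop = FALSE], regIds = ids[-j],
         targetId = ids[j])
  } else {
    if (length(target) != nrow(X))
      stop("external target must have one value per sample")
    list(y = as.numeric(target), Xreg = X, regIds = ids, targetId = "target")
  }
}

.defaultSubsetSize <- function(q) as.integer(ceiling(q / 2))

.drawRows <- function(n, nb, omega)
  matrix(sample.int(n, nb * omega, replace = TRUE), nb, omega)

#' Bootstrap-averaged coefficient adjacency
#'
#' Runs the stage-1 random-lasso ensemble with every gene in turn as the
#' target and symmetrizes the averaged coefficient matrix into the weighted
#' gene-gene adjacency \eqn{w_{kj} = (|\hat\beta^*_{kj}| +
#' |\hat\beta^*_{jk}|)/2}. This is the data-driven graph behind both the
#' centrality scores and the Laplacian penalty when no prior network is
#' supplied.
#'
#' @param X samples-by-genes matrix (standardized internally).
#' @param omega bootstrap replicates per target.
#' @param p1Star candidate-set size per replicate (`NULL`: half the pool).
#' @param seed master seed; each per-gene sweep derives its own seed from
#'   the gene id so results do not depend on column order.
#' @param config a [netrlConfig()] for solver settings.
#' @return a [WeightedGeneGraph-class].
#' @export
coefficientAdjacency <- function(X, omega = 200, p1Star = NULL, seed = 1,
                                 config = netrlConfig()) {
  X <- as.matrix(X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(X)))
  p <- ncol(X)
  B <- matrix(0, p, p)
  # per-gene sweeps regress on a pool of p-1 genes; cap the candidate size
  ps <- if (is.null(p1Star)) NULL else min(p1Star, p - 1L)
  for (k in seq_len(p)) {
    ens <- .stage1ForTarget(X[, -k, drop = FALSE], X[, k], omega, ps,
                            .targetSeed(seed, paste0("sweep:", ids[k])),
                            config)
    B[k, -k] <- rowMeans(ens$coefficients)
  }
  adjacencyFromCoefficients(B, geneIds = ids)
}

# stage-1 ensemble for one response; Xreg/y raw, standardized here
.stage1ForTarget <- function(Xreg, y, omega, p1Star, seed, config) {
  ds <- designData(Xreg, y)
  q <- ncol(ds$X)
  n <- nrow(ds$X)
  if (is.null(p1Star)) p1Star <- .defaultSubsetSize(q)
  if (p1Star > q) stop("p1Star (", p1Star, ") exceeds the regulator pool (",
                       q, ")")
  if (omega < 1) stop("omega must be at least 1")
  nb <- if (is.null(config$bootstrapSize)) n else
    min(config$bootstrapSize, n)
  sigma2 <- if (is.null(config$sigma2))
    estimateNoiseVariance(ds, config$ridgePenalty) else config$sigma2
  .withSeed(seed, {
    rows <- .drawRows(n, nb, omega)
    cands <- vapply(seq_len(omega),
                    function(i) sort(sample.int(q, p1Star)),
                    integer(p1Star))
    cands <- matrix(cands, nrow = p1Star)
    coefs <- .stage1EnsembleCpp(ds$X, ds$y, rows - 1L, cands - 1L,
                                config$nlambda, config$minRatio, sigma2,
                                config$pathTol, config$tol, config$maxit)
    structure(list(targetId = NA_character_, geneIds = ds$columnIds,
                   omega = omega, subsetSize = p1Star,
                   candidateSets = cands, sampleIndices = rows,
                   coefficients = coefs, sigma2 = sigma2, stage = 1L,
                   design = ds),
              class = "bootstrapEnsemble")
  })
}

#' @export
print.bootstrapEnsemble <- function(x, ...) {
  cat(sprintf(
    "netRL stage-%d bootstrap ensemble: %d replicates, %d-gene candidate sets, %d genes\n",
    x$stage, x$omega, x$subsetSize, length(x$geneIds)))
  invisible(x)
}

#' Stage 1: centrality-weighted gene importance
#'
#' Draws `omega` bootstrap samples, fits a BIC-tuned lasso on a uniform
#' random subset of `p1Star` regulators in each, and averages the
#' coefficients over all replicates (zeros for unsampled genes). The
#' importance of regulator j combines this statistical signal with network
#' topology: \deqn{C_j = \frac{H_j + B_j}{2}\,\Big|\frac{1}{\Omega}
#' \sum_\omega \hat\beta_{\ell j}^{(\omega)}\Big|,} where hubness
#' \eqn{H_j} and betweenness \eqn{B_j} are computed on the binarized
#' gene-gene adjacency (a supplied prior network, the bootstrap-averaged
#' coefficient adjacency, or the absolute correlation matrix, per
#' `config$adjacency`).
#'
#' @param X samples-by-genes expression matrix.
#' @param target a gene id/index in `X`, or an external numeric response of
#'   length `nrow(X)` (then every column of `X` is a candidate regulator).
#' @param omega bootstrap replicates.
#' @param p1Star candidate-set size (`NULL`: half the regulator pool).
#' @param prior optional [WeightedGeneGraph-class] overriding the
#'   config adjacency.
#' @param seed integer seed.
#' @param config a [netrlConfig()].
#' @return a `geneImportance` list: `C`, `H`, `B`, `meanBeta`,
#'   `meanAbsBeta`, the stage-1 `ensemble`, and the `graph` used.
#' @export
stage1Importance <- function(X, target, omega = 200, p1Star = NULL,
                             prior = NULL, seed = 1,
                             config = netrlConfig(omega = omega)) {
  tg <- .resolveTarget(X, target)
  ens <- .stage1ForTarget(tg$Xreg, tg$y, omega, p1Star, seed, config)
  ens$targetId <- tg$targetId
  meanBeta <- rowMeans(ens$coefficients)
  if (!is.null(prior)) {
    graph <- prior
  } else if (config$adjacency == "prior") {
    graph <- config$prior
  } else if (config$adjacency == "corr") {
    graph <- adjacencyFromCorrelation(ens$design$X)
  } else {
    graph <- coefficientAdjacency(tg$Xreg, omega = omega,
                                  p1Star = ens$subsetSize,
                                  seed = seed, config = config)
  }
  if (!identical(geneIds(graph), ens$geneIds)) {
    idx <- match(ens$geneIds, geneIds(graph))
    if (anyNA(idx))
      stop("adjacency graph does not cover the regulator genes")
    W <- graph@weights[idx, idx, drop = FALSE]
    graph <- new("WeightedGeneGraph", geneIds = ens$geneIds, weights = W)
  }
  q <- length(ens$geneIds)
  if (config$useCentrality) {
    A <- binarizeAdjacency(graph, 0)
    H <- hubness(A, q)
    B <- betweenness(A)
    C <- (H + B) / 2 * abs(meanBeta)
  } else {
    H <- rep(NA_real_, q); B <- rep(NA_real_, q)
    C <- abs(meanBeta)
  }
  names(C) <- ens$geneIds
  names(meanBeta) <- ens$geneIds
  structure(list(C = C, H = H, B = B, meanBeta = meanBeta,
                 meanAbsBeta = abs(meanBeta), ensemble = ens,
                 graph = graph, targetId = tg$targetId),
            class = "geneImportance")
}

#' @export
print.geneImportance <- function(x, ...) {
  cat("netRL gene importance for target", x$targetId, ":",
      sum(x$C > 0), "of", length(x$C), "regulators with positive C\n")
  invisible(x)
}

#' Importance-weighted candidate sampling
#'
#' Draws `p2Star` distinct regulator indices without replacement, each
#' successive draw with probability proportional to the gene's importance
#' \eqn{C_j} (plus a small floor so zero-importance genes keep the draw
#' feasible). Uses the current RNG stream.
#'
#' @param C nonnegative importance vector.
#' @param p2Star number of genes to draw.
#' @param floorFrac floor for zero importances as a fraction of `max(C)`;
#'   0 disables the floor. If every importance is zero and the floor is
#'   enabled, sampling falls back to uniform.
#' @return sorted integer index vector of length `p2Star`.
#' @export
weightedSubsetSample <- function(C, p2Star, floorFrac = 1e-6) {
  C <- as.numeric(C)
  if (any(C < 0)) stop("importances must be nonnegative")
  if (p2Star > length(C))
    stop("p2Star (", p2Star, ") exceeds the number of regulators")
  prob <- C
  if (max(C) > 0) {
    if (floorFrac > 0) prob[prob == 0] <- floorFrac * max(C)
  } else {
    if (floorFrac <= 0)
      stop("all importances are zero and the floor is disabled")
    prob <- rep(1, length(C))
  }
  if (sum(prob > 0) < p2Star)
    stop("fewer positive-probability genes than p2Star; enable the floor")
  sort(sample.int(length(C), p2Star, replace = FALSE, prob = prob))
}

# per-response-column BIC noise variances for stage 2: the observed column
# keeps the dataset-level estimate (or fixed override); permuted columns
# are re-estimated from their own response under the "per-column" policy so
# that a permuted rerun is treated exactly like an observed dataset
.stage2Sigma2 <- function(ds, Y, sigma2obs, config) {
  if (ncol(Y) == 1 || identical(config$sigma2Perm, "same"))
    return(sigma2obs)
  pre <- .noisePrecompute(ds$X)
  c(sigma2obs,
    vapply(seq_len(ncol(Y) - 1) + 1,
           function(cc) .noiseVarCol(pre, Y[, cc]), numeric(1)))
}

# internal: full stage-2 machinery, optionally with permuted responses.
# Returns ensemble + m counts for observed and each permutation.
.runStage2 <- function(ds, importance, Ltilde, config, seed, piReps = 0) {
  q <- ncol(ds$X)
  n <- nrow(ds$X)
  if (length(importance) != q)
    stop("importance length (", length(importance),
         ") does not match the regulator pool (", q, ")")
  p2Star <- if (is.null(config$p2Star)) .defaultSubsetSize(q) else
    as.integer(config$p2Star)
  if (p2Star > q) stop("p2Star (", p2Star, ") exceeds the regulator pool")
  nb <- if (is.null(config$bootstrapSize)) n else
    min(config$bootstrapSize, n)
  sigma2 <- if (is.null(config$sigma2))
    estimateNoiseVariance(ds, config$ridgePenalty) else config$sigma2
  .withSeed(seed, {
    rows <- .drawRows(n, nb, config$omega)
    cands <- vapply(seq_len(config$omega),
                    function(i) weightedSubsetSample(importance, p2Star,
                                                     config$floorFrac),
                    integer(p2Star))
    cands <- matrix(cands, nrow = p2Star)
    Y <- matrix(ds$y, n, 1 + piReps)
    if (piReps > 0)
      for (phi in seq_len(piReps)) Y[, 1 + phi] <- ds$y[sample.int(n)]
    sigma2 <- .stage2Sigma2(ds, Y, sigma2, config)
    res <- .stage2EnsembleCpp(ds$X, Y, rows - 1L, cands - 1L, Ltilde,
                              config$lambda2, config$nlambda,
                              config$minRatio, sigma2, config$pathTol,
                              config$tol, config$maxit)
    ens <- structure(list(targetId = NA_character_, geneIds = ds$columnIds,
                          omega = config$omega, subsetSize = p2Star,
                          candidateSets = cands, sampleIndices = rows,
                          coefficients = res$coefficients,
                          m = as.integer(res$m[, 1]),
                          candCount = as.integer(res$candCount),
                          sigma2 = sigma2, stage = 2L, design = ds,
                          Ltilde = Ltilde, config = config, seed = seed),
                     class = "bootstrapEnsemble")
    list(ensemble = ens, mPerm = if (piReps > 0)
      res$m[, -1, drop = FALSE] else NULL)
  })
}

.aggregateCoefficients <- function(ens, aggregation = "mean") {
  if (aggregation == "median") apply(ens$coefficients, 1, stats::median)
  else rowMeans(ens$coefficients)
}

#' Stage 2: network-constrained ensemble estimation
#'
#' Draws a fresh set of bootstrap samples; in each, samples `p2Star`
#' candidate regulators with probability proportional to their importance,
#' restricts the full-gene normalized Laplacian to the candidates, and fits
#' a BIC-tuned network-constrained lasso. The final edge weight of each
#' regulator is the average of its replicate coefficients over all
#' `omega` replicates (zero where it was not a candidate).
#'
#' @inheritParams stage1Importance
#' @param p2Star stage-2 candidate-set size (`NULL`: half the pool).
#' @param importance a `geneImportance` object from [stage1Importance()]
#'   (or a bare nonnegative vector).
#' @param L the full-gene [NormalizedLaplacian-class]; defaults to the
#'   Laplacian of the importance object's graph.
#' @param signReference per-gene signs in \{-1, 0, +1\} used to orient the
#'   Laplacian penalty; defaults to the signs of the stage-1 averaged
#'   coefficients.
#' @return list with `coefficients` (aggregated, full length) and the
#'   stage-2 `ensemble`.
#' @export
stage2Estimate <- function(X, target, omega = 200, p2Star = NULL,
                           importance, L = NULL, signReference = NULL,
                           seed = 1, config = netrlConfig(omega = omega)) {
  tg <- .resolveTarget(X, target)
  ds <- designData(tg$Xreg, tg$y)
  config$omega <- as.integer(omega)
  if (!is.null(p2Star)) config$p2Star <- p2Star
  if (inherits(importance, "geneImportance")) {
    impVec <- importance$C
    if (is.null(L)) L <- normalizedLaplacian(importance$graph)
    if (is.null(signReference)) signReference <- sign(importance$meanBeta)
  } else {
    impVec <- as.numeric(importance)
  }
  Lm <- if (is(L, "NormalizedLaplacian")) L@matrix else as.matrix(L)
  if (nrow(Lm) != ncol(ds$X))
    stop("Laplacian dimension does not match the regulator pool")
  Lt <- .signedLaplacian(Lm, signReference, ncol(ds$X))
  out <- .runStage2(ds, impVec, Lt, config, seed, piReps = 0)
  out$ensemble$targetId <- tg$targetId
  beta <- .aggregateCoefficients(out$ensemble, config$aggregation)
  names(beta) <- ds$columnIds
  list(coefficients = beta, ensemble = out$ensemble)
}

#' Permutation edge test
#'
#' Significance of each regulator's bootstrap selection frequency
#' \eqn{m_{\ell j} = \sum_\omega I(\hat\beta^{(\omega)}_{\ell j} \neq 0)}
#' against frequencies recomputed after permuting the target's expression:
#' \eqn{p_{\ell j} = \#\{\phi : m^{(\phi)}_{\ell j} \ge m_{\ell j}\}/\Pi}.
#' The permuted reruns reuse the observed run's bootstrap rows and
#' candidate sets, so the null is driven by the response permutation alone.
#'
#' @param observed a stage-2 `bootstrapEnsemble`.
#' @param piReps number of permutations \eqn{\Pi}.
#' @param alpha significance level for the `selected` flag.
#' @param seed seed for the permutation stream.
#' @return data.frame with `gene`, `m`, `p_perm`, `selected`.
#' @export
permutationEdgeTest <- function(observed, piReps = 100, alpha = 0.05,
                                seed = 1) {
  stopifnot(inherits(observed, "bootstrapEnsemble"), observed$stage == 2L)
  if (piReps < 1) stop("piReps must be at least 1")
  config <- observed$config
  out <- .withSeed(seed, {
    n <- nrow(observed$design$X)
    Y <- matrix(observed$design$y, n, 1 + piReps)
    for (phi in seq_len(piReps)) Y[, 1 + phi] <- observed$design$y[sample.int(n)]
    s2 <- .stage2Sigma2(observed$design, Y, observed$sigma2, config)
    .stage2EnsembleCpp(observed$design$X, Y, observed$sampleIndices - 1L,
                       observed$candidateSets - 1L, observed$Ltilde,
                       config$lambda2, config$nlambda, config$minRatio,
                       s2, config$pathTol, config$tol,
                       config$maxit)
  })
  m <- as.integer(out$m[, 1])
  mPerm <- out$m[, -1, drop = FALSE]
  p <- vapply(seq_along(m),
              function(j) sum(mPerm[j, ] >= m[j]) / piReps, numeric(1))
  data.frame(gene = observed$geneIds, m = m, p_perm = p,
             selected = p <= alpha, stringsAsFactors = FALSE)
}

#' Hypergeometric edge calibration
#'
#' Tests whether a regulator was selected across bootstrap replicates more
#' often than expected by chance under random subsampling. With
#' \eqn{N = \Omega p_2^*} candidate slots in total, \eqn{K} total nonzero
#' selections for this target, and \eqn{n_j} replicates whose candidate set
#' contained gene j, the upper-tail p-value is
#' \eqn{P\{\mathrm{Hyper}(N, K, n_j) \ge m_{\ell j}\}}.
#'
#' @param observed a stage-2 `bootstrapEnsemble`.
#' @param alpha significance level for the `selected` flag.
#' @return data.frame with `gene`, `m`, `n_j`, `p_hyper`, `selected`.
#' @export
hypergeometricEdgeTest <- function(observed, alpha = 0.05) {
  stopifnot(inherits(observed, "bootstrapEnsemble"), observed$stage == 2L)
  m <- observed$m
  nj <- observed$candCount
  if (any(m > nj))
    stop("selection count exceeds candidacy count; ensemble is inconsistent")
  N <- observed$omega * observed$subsetSize
  K <- sum(m)
  p <- stats::phyper(m - 1, K, N - K, nj, lower.tail = FALSE)
  p <- pmin(pmax(p, 0), 1)
  data.frame(gene = observed$geneIds, m = m, n_j = nj, p_hyper = p,
             selected = p <= alpha, stringsAsFactors = FALSE)
}

#' Percentile bootstrap interval filter
#'
#' Per-gene \eqn{(\alpha/2, 1-\alpha/2)} empirical quantiles of the
#' \eqn{\Omega} replicate coefficients (zeros included for replicates where
#' the gene was not a candidate); a regulator is kept iff its interval
#' excludes zero.
#'
#' @param observed a stage-2 `bootstrapEnsemble` with at least 2 replicates.
#' @param alpha interval level (0 < alpha < 1).
#' @return data.frame with `gene`, `ci_low`, `ci_high`, `selected`.
#' @export
bootstrapCiFilter <- function(observed, alpha = 0.05) {
  stopifnot(inherits(observed, "bootstrapEnsemble"), observed$stage == 2L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (observed$omega < 2) stop("need at least 2 replicates for an interval")
  qs <- apply(observed$coefficients, 1, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  lo <- qs[1, ]; hi <- qs[2, ]
  data.frame(gene = observed$geneIds, ci_low = lo, ci_high = hi,
             selected = !(lo <= 0 & hi >= 0), stringsAsFactors = FALSE)
}

#' Infer the regulators of one target gene
#'
#' Runs the full three-stage pipeline for a single target: stage-1
#' centrality-weighted importance, stage-2 network-constrained bootstrap
#' estimation, and the configured edge-significance criterion. Returns the
#' selected directed edges together with the full significance table.
#'
#' @param X samples-by-genes expression matrix.
#' @param target gene id/index in `X`, or an external response vector.
#' @param config a [netrlConfig()].
#' @param seed integer seed; the run is a pure function of
#'   `(X, target, config, seed)`.
#' @return list with elements `network` ([GeneNetwork-class] restricted to
#'   this target), `significance` (per-regulator data.frame),
#'   `coefficients`, `importance`, and the stage-2 `ensemble`.
#' @export
inferTargetNetwork <- function(X, target, config = netrlConfig(), seed = 1) {
  tg <- .resolveTarget(X, target)
  imp <- stage1Importance(X, target, omega = config$omega,
                          p1Star = config$p1Star, seed = seed,
                          config = config)
  ds <- imp$ensemble$design
  L <- normalizedLaplacian(imp$graph)
  s <- sign(imp$meanBeta)
  Lt <- .signedLaplacian(L@matrix, s, ncol(ds$X))
  piReps <- if (config$criterion == "perm") config$piReps else 0
  st2 <- .runStage2(ds, imp$C, Lt, config,
                    seed = .targetSeed(seed, paste0("stage2:", tg$targetId)),
                    piReps = piReps)
  ens <- st2$ensemble
  ens$targetId <- tg$targetId
  beta <- .aggregateCoefficients(ens, config$aggregation)

  sig <- data.frame(gene = ens$geneIds, weight = beta, m = ens$m,
                    p_perm = NA_real_, p_hyper = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE)
  if (config$criterion == "perm") {
    mPerm <- st2$mPerm
    sig$p_perm <- vapply(seq_len(nrow(sig)), function(j)
      sum(mPerm[j, ] >= ens$m[j]) / ncol(mPerm), numeric(1))
    selected <- sig$p_perm <= config$alpha
  } else if (config$criterion == "hyper") {
    ht <- hypergeometricEdgeTest(ens, config$alpha)
    sig$p_hyper <- ht$p_hyper
    selected <- ht$selected
  } else if (config$criterion == "ci") {
    ci <- bootstrapCiFilter(ens, config$alpha)
    sig$ci_low <- ci$ci_low
    sig$ci_high <- ci$ci_high
    selected <- ci$selected
  } else {
    selected <- beta != 0
  }
  sig$selected <- selected
  rownames(sig) <- NULL

  keep <- which(selected)
  edges <- data.frame(regulator = ens$geneIds[keep],
                      target = rep(tg$targetId, length(keep)),
                      weight = beta[keep],
                      m = ens$m[keep],
                      p_perm = sig$p_perm[keep],
                      p_hyper = sig$p_hyper[keep],
                      ci_low = sig$ci_low[keep],
                      ci_high = sig$ci_high[keep],
                      selected = rep(TRUE, length(keep)),
                      stringsAsFactors = FALSE)
  md <- list(omega = config$omega, p1Star = imp$ensemble$subsetSize,
             p2Star = ens$subsetSize, piReps = config$piReps,
             alpha = config$alpha, criterion = config$criterion,
             adjacency = config$adjacency, aggregation = config$aggregation,
             seed = seed)
  net <- geneNetwork(edges, geneIds = unique(c(tg$regIds, tg$targetId)),
                     metadata = md)
  list(network = net, significance = sig, coefficients = beta,
       importance = imp, ensemble = ens)
}

#' Infer a gene regulatory network over many targets
#'
#' Runs [inferTargetNetwork()] independently for each target with a
#' per-target seed derived from the master seed and the gene id (so the
#' result is invariant to target order), and unions the directed edges.
#'
#' @param X samples-by-genes expression matrix.
#' @param targets character vector of target gene ids (default: all genes).
#' @param config a [netrlConfig()].
#' @param seed master seed.
#' @param groups optional sample group labels (length `nrow(X)`); with
#'   `group` set, the analysis is restricted to that group's samples and
#'   every bootstrap draw has the size of the *smaller* group (balanced
#'   bootstrap), so networks of unequal-sized phenotypes are estimated at a
#'   common effective sample size.
#' @param group which group to analyze when `groups` is supplied.
#' @return a [GeneNetwork-class] with the union of selected edges.
#' @export
inferNetwork <- function(X, targets = NULL, config = netrlConfig(),
                         seed = 1, groups = NULL, group = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  if (!is.null(groups)) {
    if (length(groups) != nrow(X))
      stop("groups must have one label per sample")
    if (is.null(group)) stop("specify which group to analyze")
    sizes <- table(groups)
    if (!group %in% names(sizes)) stop("unknown group '", group, "'")
    config$bootstrapSize <- min(sizes)
    X <- X[groups == group, , drop = FALSE]
  }
  if (is.null(targets)) targets <- colnames(X)
  if (length(targets) == 0) stop("empty target list")
  if (!all(targets %in% colnames(X)))
    stop("targets not in X: ",
         paste(setdiff(targets, colnames(X)), collapse = ", "))
  edgeList <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    res <- inferTargetNetwork(X, targets[i], config,
                              seed = .targetSeed(seed, targets[i]))
    edgeList[[i]] <- edgeTable(res$network)
  }
  edges <- do.call(rbind, edgeList)
  md <- list(omega = config$omega, alpha = config$alpha,
             criterion = config$criterion, adjacency = config$adjacency,
             seed = seed, totalEdges = nrow(edges),
             bootstrapSize = config$bootstrapSize)
  geneNetwork(edges, geneIds = colnames(X), metadata = md)
}
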