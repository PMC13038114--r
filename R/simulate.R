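# Monte Carlo benchmark: transcription-factor block expression generator,
# support-recovery metrics, and the method-comparison driver.

#' Simulation scenario specification
#'
#' The benchmark assumes `u` transcription factors (TFs), each regulating
#' `v` child genes. TF expression is standard normal; each child is
#' bivariate-normal with its TF at correlation 0.7 (conditional
#' distribution \eqn{N(0.7 x_{TF}, 0.51)}, so the child's marginal variance
#' is 1). The target gene is a linear combination of all
#' \eqn{u \times (v+1)} regulators plus \eqn{N(0, \sigma^2)} noise.
#'
#' Situation 1 activates the first 4 TF blocks (true support smaller than
#' the training size); Situation 2 repeats the 4-block coefficient pattern
#' twice, activating 8 blocks (support larger than the training size).
#'
#' @param scenario coefficient pattern 1-4 (see [scenarioBeta()]).
#' @param situation 1 (4 active TF blocks) or 2 (8 active blocks).
#' @param u number of TFs; at least 4 (Situation 1) or 8 (Situation 2).
#' @param v child genes per TF.
#' @param sigma noise standard deviation.
#' @param n number of observations.
#' @param trainFraction fraction of rows assigned to the training split.
#' @return a `scenarioSpec` list with derived `p = u * (v + 1)`.
#' @export
scenarioSpec <- function(scenario = 1, situation = 1, u = 10, v = 10,
                         sigma = 1, n = 60, trainFraction = 0.8) {
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3 or 4")
  if (!situation %in% 1:2) stop("situation must be 1 or 2")
  minU <- if (situation == 1) 4 else 8
  if (u < minU)
    stop("situation ", situation, " needs at least ", minU, " TFs, got ", u)
  if (v < 1) stop("v must be at least 1")
  if (n < 2) stop("n must be at least 2")
  if (sigma <= 0) stop("sigma must be positive")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  structure(list(scenario = scenario, situation = situation, u = u, v = v,
                 sigma = sigma, n = n, trainFraction = trainFraction,
                 p = u * (v + 1)),
            class = "scenarioSpec")
}

# one active block: TF coefficient `a`, children a/divisor; flipped = TRUE
# negates the first 30% of the children relative to the rest
.betaBlock <- function(a, divisor, v, flipped) {
  child <- a / divisor
  if (!flipped) return(c(a, rep(child, v)))
  k <- round(0.3 * v)
  c(a, rep(-child, k), rep(child, v - k))
}

#' True coefficient vector of a simulation scenario
#'
#' Active TF blocks carry coefficients (5, -5, 3, -3); each TF's children
#' carry the TF coefficient divided by a scenario-specific divisor
#' (\eqn{\sqrt{10}} in Scenarios 1-2; \eqn{\sqrt 5} for blocks 1 and 3 and
#' \eqn{\sqrt{15}} for blocks 2 and 4 in Scenarios 3-4). Scenarios 2 and 4
#' flip the sign of the first 30% of each block's children. Situation 2
#' repeats the 4-block pattern twice. All remaining coefficients are zero.
#'
#' @param spec a [scenarioSpec()].
#' @return numeric coefficient vector of length `u * (v + 1)`, ordered as
#'   (TF1, its children, TF2, its children, ...).
#' @export
scenarioBeta <- function(spec) {
  stopifnot(inherits(spec, "scenarioSpec"))
  v <- spec$v
  flipped <- spec$scenario %in% c(2, 4)
  div <- if (spec$scenario %in% c(1, 2)) rep(sqrt(10), 4) else
    c(sqrt(5), sqrt(15), sqrt(5), sqrt(15))
  tfCoefs <- c(5, -5, 3, -3)
  blocks <- lapply(1:4, function(b)
    .betaBlock(tfCoefs[b], div[b], v, flipped))
  nActive <- if (spec$situation == 1) 4 else 8
  beta <- numeric(spec$p)
  for (b in seq_len(nActive)) {
    idx <- ((b - 1) * (v + 1) + 1):(b * (v + 1))
    beta[idx] <- blocks[[((b - 1) %% 4) + 1]]
  }
  beta
}

#' Simulate one benchmark dataset
#'
#' Generates the TF/child expression matrix, the target response
#' \eqn{y = X\beta + \epsilon}, and an 80/20 train/test split by uniform
#' row shuffle.
#'
#' @param spec a [scenarioSpec()].
#' @param seed integer seed.
#' @return a `simDataset` list: `Xtrain`, `Xtest`, `ytrain`, `ytest`,
#'   `betaTrue`, `spec`, `seed`.
#' @export
simulateDataset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "scenarioSpec"))
  betaTrue <- scenarioBeta(spec)
  .withSeed(seed, {
    n <- spec$n
    X <- matrix(0, n, spec$p)
    for (b in seq_len(spec$u)) {
      tf <- stats::rnorm(n)
      off <- (b - 1) * (spec$v + 1)
      X[, off + 1] <- tf
      for (ch in seq_len(spec$v))
        X[, off + 1 + ch] <- 0.7 * tf + stats::rnorm(n, sd = sqrt(0.51))
    }
    colnames(X) <- unlist(lapply(seq_len(spec$u), function(b)
      c(paste0("TF", b), paste0("TF", b, ".r", seq_len(spec$v)))))
    y <- as.numeric(X %*% betaTrue) + stats::rnorm(n, sd = spec$sigma)
    ord <- sample.int(n)
    nTrain <- round(spec$trainFraction * n)
    tr <- ord[seq_len(nTrain)]
    te <- ord[-seq_len(nTrain)]
    structure(list(Xtrain = X[tr, , drop = FALSE],
                   Xtest = X[te, , drop = FALSE],
                   ytrain = y[tr], ytest = y[te],
                   betaTrue = betaTrue, spec = spec, seed = seed),
              class = "simDataset")
  })
}

#' @export
print.simDataset <- function(x, ...) {
  cat(sprintf(
    "simDataset: scenario %d / situation %d, u=%d, v=%d, sigma=%g, %d train + %d test rows, %d genes (%d active)\n",
    x$spec$scenario, x$spec$situation, x$spec$u, x$spec$v, x$spec$sigma,
    nrow(x$Xtrain), nrow(x$Xtest), x$spec$p, sum(x$betaTrue != 0)))
  invisible(x)
}

#' Support-recovery metrics
#'
#' Confusion-matrix rates comparing the nonzero pattern of an estimate with
#' the true support: TPR = TP/P, TNR = TN/N, FDR = FP/(TP+FP) (0 when no
#' positives are declared), ACC = (TP+TN)/(P+N), and the declared edge
#' count TP+FP.
#'
#' @param betaHat estimated coefficients.
#' @param betaTrue true coefficients (same length).
#' @return list with `tpr`, `tnr`, `fdr`, `acc`, `edgeCount`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
selectionMetrics <- function(betaHat, betaTrue) {
  if (length(betaHat) != length(betaTrue))
    stop("betaHat and betaTrue must have equal length")
  sel <- betaHat != 0
  tru <- betaTrue != 0
  tp <- sum(sel & tru); fp <- sum(sel & !tru)
  fn <- sum(!sel & tru); tn <- sum(!sel & !tru)
  P <- tp + fn; N <- tn + fp
  list(tpr = if (P > 0) tp / P else NA_real_,
       tnr = if (N > 0) tn / N else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       acc = (tp + tn) / (P + N),
       edgeCount = tp + fp, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Test-set mean squared prediction error
#'
#' Mean over test rows of \eqn{(y - \hat y)^2}, where predictions use
#' coefficients on the standardized-training scale mapped back through the
#' training centering/scaling constants.
#'
#' @param betaHat coefficients on the standardized training scale.
#' @param dataset a `simDataset`.
#' @param design optionally, the [designData()] built from the training
#'   split (recomputed if omitted).
#' @return scalar MSE.
#' @export
testMse <- function(betaHat, dataset, design = NULL) {
  stopifnot(inherits(dataset, "simDataset"))
  if (nrow(dataset$Xtest) == 0) stop("empty test split")
  if (is.null(design)) design <- designData(dataset$Xtrain, dataset$ytrain)
  Xs <- sweep(sweep(dataset$Xtest, 2, design$center, "-"), 2,
              design$scale, "/")
  pred <- design$yCenter + as.numeric(Xs %*% betaHat)
  mean((dataset$ytest - pred)^2)
}

.benchmarkMethods <- c("lasso", "adaptive-lasso", "elastic-net",
                       "random-lasso", "netRL-beta", "netRL-corr")

# fit one method on one dataset; returns standardized-scale coefficients
# with unselected entries zeroed, plus the criterion label used
.fitBenchmarkMethod <- function(method, dataset, config, seed) {
  ds <- designData(dataset$Xtrain, dataset$ytrain)
  grid <- penaltyGrid(lambda2 = config$lambda2, nlambda = config$nlambda,
                      minRatio = config$minRatio)
  if (method %in% c("lasso", "adaptive-lasso", "elastic-net")) {
    fit <- selectByBIC(ds, grid, method = method, sigma2 = config$sigma2,
                       ridgePenalty = config$ridgePenalty)
    return(list(beta = coef(fit), criterion = "none", design = ds))
  }
  cfg <- config
  if (method == "random-lasso") {
    cfg$useCentrality <- FALSE
    cfg$lambda2 <- 0
    cfg$adjacency <- "corr" # graph unused; keeps stage 1 cheap
    cfg$criterion <- "none"
  } else if (method == "netRL-beta") {
    cfg$adjacency <- "beta"
  } else if (method == "netRL-corr") {
    cfg$adjacency <- "corr"
  } else {
    stop("unknown method id '", method, "'")
  }
  res <- inferTargetNetwork(dataset$Xtrain, dataset$ytrain, cfg, seed = seed)
  beta <- res$coefficients
  beta[!res$significance$selected] <- 0
  list(beta = beta, criterion = cfg$criterion, design = res$ensemble$design)
}

#' Run the Monte Carlo benchmark
#'
#' Simulates `nDatasets` datasets per scenario specification and evaluates
#' each requested method on every dataset, averaging the support-recovery
#' metrics and the test MSE.
#'
#' @param methods character vector from `lasso`, `adaptive-lasso`,
#'   `elastic-net`, `random-lasso`, `netRL-beta`, `netRL-corr`.
#' @param specs a [scenarioSpec()] or list of them.
#' @param nDatasets simulated datasets per spec.
#' @param seed master seed; dataset d uses seed `seed + d - 1` so results
#'   do not depend on evaluation order.
#' @param config a [netrlConfig()] (criterion, omega, piReps, grids) used
#'   by the bootstrap-ensemble methods.
#' @param noiseVariance BIC noise variance \eqn{\sigma^2}: `"known"`
#'   (default) plugs in the generator's `sigma^2` — the quantity the BIC
#'   formula refers to, which is a known design parameter in simulation —
#'   while `"estimated"` uses the data-driven plug-in
#'   ([estimateNoiseVariance()]) as one would on real data.
#' @return data.frame with one row per (spec, method): columns `situation`,
#'   `sigma`, `u`, `scenario`, `method`, `criterion`, `tpr`, `tnr`, `fdr`,
#'   `acc`, `edges`, `mse`, `n_datasets`, `omega`, `seed`.
#' @export
runBenchmark <- function(methods, specs, nDatasets = 50, seed = 1,
                         config = netrlConfig(),
                         noiseVariance = c("known", "estimated")) {
  if (inherits(specs, "scenarioSpec")) specs <- list(specs)
  noiseVariance <- match.arg(noiseVariance)
  bad <- setdiff(methods, .benchmarkMethods)
  if (length(bad))
    stop("unknown method id(s): ", paste(bad, collapse = ", "))
  rows <- list()
  for (spec in specs) {
    specConfig <- config
    if (noiseVariance == "known") specConfig$sigma2 <- spec$sigma^2
    for (method in methods) {
      acc <- matrix(NA_real_, nDatasets, 6,
                    dimnames = list(NULL, c("tpr", "tnr", "fdr", "acc",
                                            "edges", "mse")))
      crit <- "none"
      for (dIdx in seq_len(nDatasets)) {
        dset <- simulateDataset(spec, seed = seed + dIdx - 1)
        fit <- .fitBenchmarkMethod(method, dset, specConfig,
                                   seed = .targetSeed(seed + dIdx - 1,
                                                      method))
        met <- selectionMetrics(fit$beta, dset$betaTrue)
        acc[dIdx, ] <- c(met$tpr, met$tnr, met$fdr, met$acc, met$edgeCount,
                         testMse(fit$beta, dset, fit$design))
        crit <- fit$criterion
      }
      rows[[length(rows) + 1]] <- data.frame(
        situation = spec$situation, sigma = spec$sigma, u = spec$u,
        scenario = spec$scenario, method = method, criterion = crit,
        tpr = mean(acc[, "tpr"]), tnr = mean(acc[, "tnr"]),
        fdr = mean(acc[, "fdr"]), acc = mean(acc[, "acc"]),
        edges = mean(acc[, "edges"]), mse = mean(acc[, "mse"]),
        n_datasets = nDatasets, omega = config$omega, seed = seed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
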