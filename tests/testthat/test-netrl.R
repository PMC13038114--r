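# The three-stage pipeline: importance, ensemble estimation, significance.

smallData <- function(seed = 1, n = 40, p = 12, strong = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("g", seq_len(p))
  beta <- c(rep(4, strong), rep(0, p - strong))
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, beta = beta)
}

test_that("importance combines centralities and averaged coefficients", {
  # arithmetic of the importance measure on hand-built inputs
  H <- c(0.6, 0.6); B <- c(0.4, 0.4); meanBeta <- c(1, -3)
  C <- (H + B) / 2 * abs(meanBeta)
  expect_equal(C, c(0.5, 1.5))

  # an isolated gene (H = B = 0) has zero importance whatever its weight
  d <- smallData(2)
  prior <- new("WeightedGeneGraph", geneIds = colnames(d$X),
               weights = matrix(0, 12, 12)) # empty graph: all centralities 0
  imp <- stage1Importance(d$X, d$y, omega = 5, prior = prior, seed = 3,
                          config = netrlConfig(omega = 5, sigma2 = 1))
  expect_equal(unname(imp$C), rep(0, 12))
  expect_equal(unname(imp$H), rep(0, 12))

  # with a real run, C_j = (H_j+B_j)/2 * |mean beta| to machine precision
  imp2 <- stage1Importance(d$X, d$y, omega = 10, seed = 3,
                           config = netrlConfig(omega = 10, sigma2 = 1))
  expect_equal(unname(imp2$C),
               unname((imp2$H + imp2$B) / 2 * abs(imp2$meanBeta)),
               tolerance = 1e-12)
  expect_true(all(imp2$H >= 0 & imp2$H <= 1))
  expect_true(all(imp2$B >= 0 & imp2$B <= 1))
})

test_that("stage-1 ensembles respect candidate sets and sizes", {
  d <- smallData(4)
  cfg <- netrlConfig(omega = 8, sigma2 = 1)
  imp <- stage1Importance(d$X, d$y, omega = 8, p1Star = 5, seed = 9,
                          config = cfg)
  ens <- imp$ensemble
  expect_equal(ncol(ens$coefficients), 8)
  expect_equal(nrow(ens$candidateSets), 5)
  for (w in 1:8) {
    outside <- setdiff(seq_len(12), ens$candidateSets[, w])
    expect_true(all(ens$coefficients[outside, w] == 0))
  }
  expect_error(stage1Importance(d$X, d$y, omega = 5, p1Star = 13, seed = 1,
                                config = cfg),
               "exceeds")
  expect_error(stage1Importance(d$X, d$y, omega = 0, seed = 1, config = cfg),
               "omega")
})

test_that("weighted subset sampling follows the importance distribution", {
  set.seed(20)
  # degenerate: all mass on one gene
  expect_equal(weightedSubsetSample(c(1, 0, 0), 1, floorFrac = 0), 1L)
  expect_error(weightedSubsetSample(c(0, 0, 0), 1, floorFrac = 0), "zero")
  expect_error(weightedSubsetSample(c(1, 2), 3), "exceeds")

  # equal importances: uniform inclusion over many draws
  counts <- integer(6)
  for (i in 1:6000) {
    s <- weightedSubsetSample(rep(2, 6), 2)
    counts[s] <- counts[s] + 1
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)

  # C = (2,1,1), one draw: gene 1 frequency ~ 0.5
  hits <- 0
  for (i in 1:10000) hits <- hits + (weightedSubsetSample(c(2, 1, 1), 1) == 1)
  expect_lt(abs(hits / 10000 - 0.5), 0.02)
})

test_that("stage-2 aggregation is the exact replicate mean", {
  # replicate-mean aggregation: values (0, 4) average to 2
  expect_equal(mean(c(0, 4)), 2)

  d <- smallData(6)
  cfg <- netrlConfig(omega = 10, sigma2 = 1, criterion = "none")
  imp <- stage1Importance(d$X, d$y, omega = 10, seed = 5, config = cfg)
  st2 <- stage2Estimate(d$X, d$y, omega = 10, importance = imp, seed = 5,
                        config = cfg)
  expect_equal(unname(st2$coefficients),
               unname(rowMeans(st2$ensemble$coefficients)))
  expect_equal(max(abs(st2$coefficients -
                         rowMeans(st2$ensemble$coefficients))), 0)
  # zeros outside candidate sets
  for (w in 1:10) {
    outside <- setdiff(seq_len(12), st2$ensemble$candidateSets[, w])
    expect_true(all(st2$ensemble$coefficients[outside, w] == 0))
  }
  expect_error(stage2Estimate(d$X, d$y, omega = 5, importance = rep(1, 3),
                              L = diag(12), seed = 1, config = cfg),
               "importance length")
})

test_that("degenerate configuration reduces to a single BIC-tuned lasso", {
  d <- smallData(7, n = 30, p = 8)
  cfg <- netrlConfig(omega = 1, p1Star = 8, p2Star = 8, lambda2 = 0,
                     criterion = "none", sigma2 = 1, floorFrac = 1e-6)
  res <- inferTargetNetwork(d$X, d$y, cfg, seed = 2)
  # omega = 1 with full candidate sets and lambda2 = 0: one lasso fit on
  # one bootstrap resample; verify against a direct fit on the same rows
  rows <- res$ensemble$sampleIndices[, 1]
  ds <- designData(d$X, d$y)
  dboot <- designData(ds$X[rows, , drop = FALSE], ds$y[rows],
                      standardize = FALSE)
  direct <- selectByBIC(dboot, penaltyGrid(lambda2 = 0), method = "lasso",
                        sigma2 = 1)
  expect_equal(unname(res$coefficients), unname(coef(direct)),
               tolerance = 1e-6)
})

test_that("permutation p-values count exceedances and are monotone in m", {
  # direct formula cases
  mPerm <- c(3, 9, 8)
  expect_equal(sum(mPerm >= 8) / 3, 2 / 3)
  expect_equal(sum(mPerm >= 0) / 3, 1) # m = 0 always gives p = 1

  d <- smallData(8)
  cfg <- netrlConfig(omega = 12, piReps = 20, sigma2 = 1)
  imp <- stage1Importance(d$X, d$y, omega = 12, seed = 4, config = cfg)
  st2 <- stage2Estimate(d$X, d$y, omega = 12, importance = imp, seed = 4,
                        config = cfg)
  pt <- permutationEdgeTest(st2$ensemble, piReps = 20, alpha = 0.05,
                            seed = 11)
  expect_true(all(pt$p_perm >= 0 & pt$p_perm <= 1))
  expect_true(all(pt$m >= 0 & pt$m <= 12))
  expect_error(permutationEdgeTest(st2$ensemble, piReps = 0), "piReps")

  # monotonicity: recomputing p with a larger m (same permuted counts)
  # cannot increase it
  mp <- matrix(sample(0:12, 12 * 20, replace = TRUE), 12, 20)
  for (j in 1:12) {
    ps <- vapply(0:12, function(m) sum(mp[j, ] >= m) / 20, numeric(1))
    expect_true(all(diff(ps) <= 0))
  }
})

test_that("hypergeometric calibration matches exhaustive enumeration", {
  # Omega = 3 replicates, p2* = 2, three genes; gene 1 in every candidate
  # set and selected every time; no other selections
  d <- smallData(9, p = 3, strong = 1)
  cfg <- netrlConfig(omega = 3, p2Star = 2, sigma2 = 1)
  ens <- structure(list(targetId = "y", geneIds = paste0("g", 1:3),
                        omega = 3L, subsetSize = 2L,
                        candidateSets = matrix(c(1, 2, 1, 3, 1, 2), 2),
                        coefficients = matrix(0, 3, 3),
                        m = c(3L, 0L, 0L), candCount = c(3L, 2L, 1L),
                        sigma2 = 1, stage = 2L, config = cfg),
                   class = "bootstrapEnsemble")
  ht <- hypergeometricEdgeTest(ens)
  # N = 6 slots, K = 3 successes, gene 1: n_j = 3, m = 3.
  # Exhaustive: P(all 3 successes land in gene 1's slots) = 1/C(6,3)
  expect_equal(ht$p_hyper[1], 1 / choose(6, 3))
  expect_equal(ht$p_hyper[2], 1) # m = 0 -> upper tail at 0 is 1
  expect_equal(ht$p_hyper[3], 1)

  # K = N (every slot a success): p = 1 for every gene
  ens2 <- ens
  ens2$m <- c(3L, 2L, 1L)
  ht2 <- hypergeometricEdgeTest(ens2)
  expect_equal(ht2$p_hyper, rep(1, 3))

  # m > n_j is an invariant violation
  ens3 <- ens
  ens3$m <- c(3L, 3L, 0L)
  expect_error(hypergeometricEdgeTest(ens3), "candidacy")

  # monotone in m with everything else fixed
  N <- 40; K <- 12; nj <- 10
  ps <- stats::phyper(0:10 - 1, K, N - K, nj, lower.tail = FALSE)
  expect_true(all(diff(ps) <= 0))
})

test_that("percentile interval filter matches quantile conventions", {
  d <- smallData(10, p = 4, strong = 1)
  cfg <- netrlConfig(omega = 100, p2Star = 2, sigma2 = 1)
  ens <- structure(list(targetId = "y", geneIds = paste0("g", 1:4),
                        omega = 100L, subsetSize = 2L,
                        candidateSets = matrix(1L, 2, 100),
                        coefficients = rbind(1:100,
                                             rep(0, 100),
                                             c(-(1:50), 1:50),
                                             rep(0, 100)),
                        m = integer(4), candCount = integer(4),
                        sigma2 = 1, stage = 2L, config = cfg),
                   class = "bootstrapEnsemble")
  ci <- bootstrapCiFilter(ens, alpha = 0.05)
  # type-7 quantiles of 1..100 at (0.025, 0.975)
  expect_equal(ci$ci_low[1], 3.475)
  expect_equal(ci$ci_high[1], 97.525)
  expect_true(ci$selected[1])
  expect_equal(ci$ci_low[2], 0); expect_equal(ci$ci_high[2], 0)
  expect_false(ci$selected[2]) # all-zero interval includes 0
  expect_false(ci$selected[3]) # symmetric about 0
  ens$omega <- 1L
  expect_error(bootstrapCiFilter(ens), "2 replicates")
})

test_that("full inference is deterministic and recovers a strong signal", {
  d <- smallData(12, n = 50, p = 10, strong = 3)
  cfg <- netrlConfig(omega = 20, piReps = 20, criterion = "perm", sigma2 = 1)
  r1 <- inferTargetNetwork(d$X, d$y, cfg, seed = 5)
  r2 <- inferTargetNetwork(d$X, d$y, cfg, seed = 5)
  expect_identical(edgeTable(r1$network), edgeTable(r2$network))
  expect_identical(r1$significance, r2$significance)
  # the three strong regulators are found
  expect_true(all(paste0("g", 1:3) %in% edgeTable(r1$network)$regulator))
  # no self-edges, weights present only for selected
  expect_false("target" %in% edgeTable(r1$network)$regulator)
  expect_true(all(edgeTable(r1$network)$selected))
})

test_that("network inference over targets is order-invariant and additive", {
  set.seed(30)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- paste0("g", 1:6)
  X[, 2] <- X[, 1] * 0.9 + rnorm(40, sd = 0.3)
  cfg <- netrlConfig(omega = 6, criterion = "ci", alpha = 0.1, sigma2 = 1)
  netA <- inferNetwork(X, targets = c("g1", "g3", "g5"), config = cfg,
                       seed = 7)
  netB <- inferNetwork(X, targets = c("g5", "g1", "g3"), config = cfg,
                       seed = 7)
  ea <- edgeTable(netA); eb <- edgeTable(netB)
  key <- function(e) paste(e$regulator, e$target)
  expect_setequal(key(ea), key(eb))
  expect_equal(ea$weight[order(key(ea))], eb$weight[order(key(eb))])
  # additivity: union edge count equals the sum of per-target counts
  perTarget <- vapply(c("g1", "g3", "g5"), function(tg)
    nrow(edgeTable(inferTargetNetwork(X, tg, cfg,
                                      seed = netRL:::.targetSeed(7, tg))$network)),
    numeric(1))
  expect_equal(nrow(ea), sum(perTarget))
  expect_equal(networkMetadata(netA)$totalEdges, nrow(ea))
  expect_error(inferNetwork(X, targets = character(), config = cfg), "empty")
})

test_that("balanced bootstrap uses the smaller group size", {
  set.seed(31)
  X <- matrix(rnorm(60 * 5), 60, 5)
  colnames(X) <- paste0("g", 1:5)
  groups <- rep(c("severe", "mild"), c(40, 20))
  cfg <- netrlConfig(omega = 4, criterion = "none", sigma2 = 1)
  net <- inferNetwork(X, targets = "g1", config = cfg, seed = 3,
                      groups = groups, group = "severe")
  expect_equal(networkMetadata(net)$bootstrapSize, 20)
  # the underlying ensemble draws exactly min(nS, nN) rows per replicate
  cfg$bootstrapSize <- 20
  res <- inferTargetNetwork(X[groups == "severe", ], "g1", cfg, seed = 3)
  expect_equal(nrow(res$ensemble$sampleIndices), 20)
  expect_true(all(res$ensemble$sampleIndices <= 40))
})
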