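# Penalized regression solvers and BIC selection.

test_that("lasso reduces to OLS at lambda1 = 0 and dies at lambda_max", {
  set.seed(1)
  d <- randomDesign(40, 6)
  ols <- qr.coef(qr(d$X), d$y)
  expect_equal(unname(coef(fitLasso(d, 0))), unname(ols), tolerance = 1e-5)

  lmax <- max(abs(crossprod(d$X, d$y)))
  f <- fitLasso(d, lmax * (1 + 1e-10))
  expect_equal(unname(coef(f)), rep(0, 6))
  expect_equal(f$df, 0)
  expect_error(fitLasso(d, -1), "nonnegative")
})

test_that("lasso on orthonormal columns is exact soft-thresholding", {
  set.seed(2)
  X <- qr.Q(qr(matrix(rnorm(30 * 5), 30, 5)))
  y <- rnorm(30)
  d <- designData(X, y, standardize = FALSE)
  z <- drop(crossprod(X, y))
  lam <- 0.1
  soft <- sign(z) * pmax(abs(z) - lam, 0)
  expect_equal(unname(coef(fitLasso(d, lam))), soft, tolerance = 1e-7)
})

test_that("lasso KKT conditions hold at the solution", {
  set.seed(3)
  for (i in 1:10) {
    d <- randomDesign(30, sample(4:12, 1))
    lam <- runif(1, 0.5, 5)
    beta <- coef(fitLasso(d, lam))
    r <- drop(crossprod(d$X, d$y - d$X %*% beta))
    active <- beta != 0
    if (any(active))
      expect_lt(max(abs(r[active] - lam * sign(beta[active]))), 1e-5)
    if (any(!active))
      expect_lt(max(abs(r[!active])) - lam, 1e-5)
  }
})

test_that("solvers match the exact sign-pattern oracle on small problems", {
  set.seed(4)
  for (i in 1:20) {
    q <- sample(2:4, 1)
    d <- randomDesign(15, q)
    lam1 <- runif(1, 0.2, 3)
    # lasso
    o <- signPatternOracle(d$X, d$y, lam1)
    f <- fitLasso(d, lam1)
    objF <- 0.5 * f$rss + lam1 * sum(abs(coef(f)))
    expect_lt(objF, o$objective * (1 + 1e-6) + 1e-8)
    expect_equal(unname(coef(f)), o$beta, tolerance = 1e-4)
    # network lasso with a random Laplacian and signs
    g <- randomGraph(q, 0.8)
    L <- normalizedLaplacian(g)
    s <- sample(c(-1, 1), q, replace = TRUE)
    lam2 <- runif(1, 0.1, 2)
    Lt <- L@matrix * tcrossprod(s)
    on <- signPatternOracle(d$X, d$y, lam1, lam2 = lam2, L = Lt)
    fn <- fitNetworkLasso(d, lam1, lam2, L, signReference = s)
    objN <- 0.5 * fn$rss + lam1 * sum(abs(coef(fn))) +
      lam2 * drop(t(coef(fn)) %*% Lt %*% coef(fn))
    expect_lt(objN, on$objective * (1 + 1e-6) + 1e-8)
    expect_equal(unname(coef(fn)), on$beta, tolerance = 1e-4)
  }
})

test_that("solvers agree with glmnet on a shared objective", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  d <- randomDesign(50, 8)
  n <- nrow(d$X)
  lam <- 2.5
  g <- glmnet::glmnet(d$X, d$y, lambda = lam / n, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_equal(unname(coef(fitLasso(d, lam))), as.numeric(g$beta),
               tolerance = 1e-6)
  # elastic net: glmnet's single-lambda mixed fit is not the exact
  # minimizer of the lambda1*(0.5*(1-delta)*b^2 + delta*|b|) objective, so
  # compare objective values rather than coefficients
  delta <- 0.4
  ge <- glmnet::glmnet(d$X, d$y, lambda = lam / n, alpha = delta,
                       standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  obj <- function(b)
    0.5 * sum((d$y - d$X %*% b)^2) +
      lam * sum(0.5 * (1 - delta) * b^2 + delta * abs(b))
  expect_lte(obj(coef(fitElasticNet(d, lam, delta))),
             obj(as.numeric(ge$beta)) + 1e-8)
})

test_that("adaptive lasso handles weights, exclusions, and reductions", {
  set.seed(6)
  d <- randomDesign(40, 5)
  # unit weights reduce to the plain lasso
  expect_equal(coef(fitAdaptiveLasso(d, 2, weights = rep(1, 5))),
               coef(fitLasso(d, 2)), tolerance = 1e-7)
  # lambda1 = 0 is OLS
  ols <- qr.coef(qr(d$X), d$y)
  expect_equal(unname(coef(fitAdaptiveLasso(d, 0))), unname(ols),
               tolerance = 1e-5)
  # infinite weight excludes the predictor entirely
  w <- c(Inf, rep(1, 4))
  f <- fitAdaptiveLasso(d, 0.5, weights = w)
  expect_identical(unname(coef(f))[1], 0)
  # a huge-initial-coefficient predictor is penalized least: it survives a
  # penalty that kills everything else
  o <- signPatternOracle(d$X, d$y, 4, w = c(10, 10, 0.01, 10, 10))
  f2 <- fitAdaptiveLasso(d, 4, weights = c(10, 10, 0.01, 10, 10))
  expect_equal(unname(coef(f2)), o$beta, tolerance = 1e-4)
  # OLS weights are refused when q >= n
  dwide <- randomDesign(4, 6)
  expect_error(fitAdaptiveLasso(dwide, 1, weightSource = "ols"), "ridge")
})

test_that("elastic net recovers its ridge and lasso limits", {
  set.seed(7)
  d <- randomDesign(30, 6)
  expect_equal(coef(fitElasticNet(d, 3, 1)), coef(fitLasso(d, 3)),
               tolerance = 1e-7)
  ridge <- solve(crossprod(d$X) + 3 * diag(6), crossprod(d$X, d$y))
  expect_equal(unname(coef(fitElasticNet(d, 3, 0))), drop(ridge),
               tolerance = 1e-6)
  # grouping: identical columns get equal coefficients
  X <- matrix(rnorm(60), 30, 2)
  X <- cbind(X[, 1], X[, 1], X[, 2])
  y <- X[, 1] + rnorm(30, sd = 0.1)
  di <- designData(X, y, standardize = FALSE)
  fi <- fitElasticNet(di, 2, 0.5)
  expect_equal(coef(fi)[[1]], coef(fi)[[2]], tolerance = 1e-5)
  expect_error(fitElasticNet(d, 1, 1.2), "delta")
})

test_that("network lasso reduces to lasso with no graph penalty", {
  set.seed(8)
  d <- randomDesign(25, 5)
  L <- normalizedLaplacian(randomGraph(5, 0.6))
  expect_equal(coef(fitNetworkLasso(d, 2, 0, L)), coef(fitLasso(d, 2)),
               tolerance = 1e-7)
  # empty graph: zero Laplacian, any lambda2
  L0 <- normalizedLaplacian(adjacencyFromCoefficients(matrix(0, 5, 5)))
  expect_equal(coef(fitNetworkLasso(d, 2, 50, L0)), coef(fitLasso(d, 2)),
               tolerance = 1e-7)
  expect_error(fitNetworkLasso(d, 1, 1, -diag(5)), "semidefinite")
  expect_error(fitNetworkLasso(d, 1, 1, diag(3)), "dimension")
})

test_that("large Laplacian penalty fuses connected identical predictors", {
  set.seed(9)
  x <- rnorm(40)
  X <- cbind(x, x + rnorm(40, sd = 1e-8))
  y <- 2 * x + rnorm(40, sd = 0.2)
  d <- designData(X, y)
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  L <- normalizedLaplacian(new("WeightedGeneGraph",
                               geneIds = c("a", "b"), weights = W))
  f <- fitNetworkLasso(d, 0.5, 1e4, L, signReference = c(1, 1))
  expect_lt(abs(coef(f)[[1]] - coef(f)[[2]]), 1e-4)
})

test_that("solutions beat random feasible points", {
  set.seed(10)
  d <- randomDesign(25, 6)
  lam1 <- 1.5; lam2 <- 0.5
  L <- normalizedLaplacian(randomGraph(6, 0.5))
  f <- fitNetworkLasso(d, lam1, lam2, L)
  Lt <- L@matrix
  obj <- function(beta)
    0.5 * sum((d$y - d$X %*% beta)^2) + lam1 * sum(abs(beta)) +
      lam2 * drop(t(beta) %*% Lt %*% beta)
  fObj <- obj(coef(f))
  for (i in 1:500) {
    cand <- coef(f) + rnorm(6, sd = runif(1, 0.001, 1))
    expect_gte(obj(cand), fObj - 1e-8)
  }
})

test_that("BIC follows its defining formula", {
  set.seed(11)
  # perfect fit with df = 3 on n = 10: only the complexity term remains
  X <- matrix(rnorm(30), 10, 3)
  beta <- c(1, -2, 3)
  y <- drop(X %*% beta)
  d <- designData(X, y, standardize = FALSE)
  f <- fitLasso(d, 0)
  expect_equal(bicScore(f, d, 1), 3 * log(10) / 10, tolerance = 1e-6)
  # null model: ||y||^2 / (n sigma2)
  fnull <- fitLasso(d, 1e6)
  expect_equal(bicScore(fnull, d, 2), sum(d$y^2) / (10 * 2))
  # direct re-computation on an arbitrary fit
  d2 <- randomDesign(20, 5)
  f2 <- fitLasso(d2, 1)
  manual <- sum((d2$y - d2$X %*% coef(f2))^2) / (20 * 1.3) +
    log(20) / 20 * sum(coef(f2) != 0)
  expect_equal(bicScore(f2, d2, 1.3), manual)
  expect_error(bicScore(f2, d2, 0), "positive")
})

test_that("BIC grid selection minimizes and breaks ties toward sparsity", {
  set.seed(12)
  d <- randomDesign(30, 5)
  # single-point grid returns that fit
  g1 <- penaltyGrid(lambda1 = 2, lambda2 = 0)
  f1 <- selectByBIC(d, g1, method = "lasso", sigma2 = 1)
  expect_equal(coef(f1), coef(fitLasso(d, 2)), tolerance = 1e-6)

  # enumerate the grid by hand and compare the minimum
  grid <- penaltyGrid(lambda1 = c(8, 4, 2, 1, 0.5), lambda2 = 0)
  best <- NULL; bestBic <- Inf
  for (l1 in grid$lambda1) {
    f <- fitLasso(d, l1)
    bb <- bicScore(f, d, 1)
    if (bb < bestBic - 1e-12) { bestBic <- bb; best <- f }
  }
  fsel <- selectByBIC(d, grid, method = "lasso", sigma2 = 1)
  expect_equal(fsel$lambda1, best$lambda1)
  expect_equal(coef(fsel), coef(best), tolerance = 1e-6)

  # tie rule: two lambda1 values that both zero every coefficient have
  # identical BIC; the larger lambda1 must win
  lmax <- max(abs(crossprod(d$X, d$y)))
  gt <- penaltyGrid(lambda1 = c(4 * lmax, 2 * lmax), lambda2 = 0)
  ft <- selectByBIC(d, gt, method = "lasso", sigma2 = 1)
  expect_equal(ft$lambda1, 4 * lmax)

  # pure-noise response: sparser model wins over the saturated one
  set.seed(13)
  Xn <- matrix(rnorm(200), 40, 5)
  dn <- designData(Xn, rnorm(40))
  gn <- penaltyGrid(lambda1 = c(max(abs(crossprod(dn$X, dn$y))) + 1, 0),
                    lambda2 = 0)
  fn <- selectByBIC(dn, gn, method = "lasso", sigma2 = 1)
  expect_equal(fn$df, 0)
})

test_that("df is monotone non-increasing in lambda1 along a path", {
  set.seed(14)
  d <- randomDesign(30, 8)
  lams <- exp(seq(log(20), log(0.01), length.out = 30))
  dfs <- vapply(lams, function(l) fitLasso(d, l)$df, numeric(1))
  expect_true(all(diff(dfs) >= 0)) # lambda decreasing -> df non-decreasing
})

test_that("noise variance plug-in tracks the truth on null and low-dim data", {
  set.seed(15)
  # overdetermined: OLS residual variance
  X <- matrix(rnorm(400), 100, 4)
  y <- drop(X %*% c(1, 2, 0, -1)) + rnorm(100, sd = 2)
  d <- designData(X, y)
  expect_equal(estimateNoiseVariance(d), 4, tolerance = 0.8)
  # high-dimensional pure noise
  Xw <- matrix(rnorm(48 * 100), 48, 100)
  dw <- designData(Xw, rnorm(48, sd = 3))
  s2 <- estimateNoiseVariance(dw)
  expect_gt(s2, 2); expect_lt(s2, 25)
})
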