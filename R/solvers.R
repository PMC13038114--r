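#' Standardized regression design
#'
#' Centers the response and centers/unit-scales each predictor column
#' (sample standard deviation, denominator n-1), which is the scale all
#' penalized fits operate on. The centering/scaling constants are kept so
#' predictions can be mapped back to the raw scale.
#'
#' @param X samples-by-predictors numeric matrix.
#' @param y numeric response of length `nrow(X)`.
#' @param standardize if `FALSE` the data are used as-is and the object is
#'   flagged raw.
#' @return an object of class `designData` with elements `X`, `y`,
#'   `columnIds`, `center`, `scale`, `yCenter`, `raw`.
#' @export
designData <- function(X, y, standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("X and y must be finite and free of NA")
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("x", seq_len(ncol(X)))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl < 1e-12] <- 1 # constant column: centered to zero, never selected
    X <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
    yc <- mean(y)
    y <- y - yc
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X)); yc <- 0
  }
  structure(list(X = X, y = y, columnIds = ids, center = ctr, scale = scl,
                 yCenter = yc, raw = !standardize),
            class = "designData")
}

.asDesign <- function(d) {
  if (!inherits(d, "designData")) stop("expected a designData object")
  d
}

.newFit <- function(d, beta, lambda1, lambda2 = 0, delta = NA_real_,
                    method = "lasso", bic = NA_real_, sigma2 = NA_real_) {
  beta <- as.numeric(beta)
  names(beta) <- d$columnIds
  r <- d$y - as.numeric(d$X %*% beta)
  structure(list(coefficients = beta, lambda1 = lambda1, lambda2 = lambda2,
                 delta = delta, df = sum(beta != 0), rss = sum(r^2),
                 method = method, bic = bic, sigma2 = sigma2,
                 n = nrow(d$X)),
            class = "netrlFit")
}

#' @export
print.netrlFit <- function(x, ...) {
  cat(sprintf("netRL penalized fit (%s): %d nonzero of %d, lambda1=%.4g",
              x$method, x$df, length(x$coefficients), x$lambda1))
  if (!is.na(x$delta)) cat(sprintf(", delta=%.2g", x$delta))
  if (x$lambda2 != 0) cat(sprintf(", lambda2=%.4g", x$lambda2))
  cat(sprintf(", rss=%.4g\n", x$rss))
  invisible(x)
}

#' @export
coef.netrlFit <- function(object, ...) object$coefficients

.cdControl <- function(tol = 1e-7, maxit = 1e5, pathTol = 1e-4)
  list(tol = tol, maxit = maxit, pathTol = pathTol)

#' Lasso fit at a fixed penalty
#'
#' Minimizes \eqn{\frac12\|y - X\beta\|^2 + \lambda_1\|\beta\|_1} by cyclic
#' coordinate descent on the Gram matrix.
#'
#' @param d a [designData()] object.
#' @param lambda1 nonnegative L1 penalty weight.
#' @param control solver control, see internals (`tol`, `maxit`).
#' @return a `netrlFit`.
#' @export
fitLasso <- function(d, lambda1, control = .cdControl()) {
  d <- .asDesign(d)
  if (!is.numeric(lambda1) || length(lambda1) != 1 || is.na(lambda1) ||
      lambda1 < 0)
    stop("lambda1 must be a single nonnegative number")
  H <- crossprod(d$X)
  b <- crossprod(d$X, d$y)
  beta <- .cdSolveCpp(H, b, lambda1, rep(1, ncol(d$X)), 0,
                      numeric(ncol(d$X)), control$tol, control$maxit)
  .newFit(d, beta, lambda1, method = "lasso")
}

#' Adaptive lasso fit
#'
#' Weighted L1 penalty \eqn{\lambda_1 \sum_j w_j |\beta_j|} with
#' \eqn{w_j = 1/|\hat\beta_{\mathrm{init},j}|} from an OLS (when q < n) or
#' ridge initial estimate. Predictors whose initial estimate is exactly zero
#' receive infinite weight and are excluded.
#'
#' @inheritParams fitLasso
#' @param weightSource `"ols"` or `"ridge"`; `"ols"` requires q < n.
#' @param ridgePenalty ridge penalty used for the initial estimate when
#'   `weightSource = "ridge"` (standardized-predictor scale).
#' @param weights optional explicit weight vector overriding the initial
#'   estimate (e.g. all ones reduces to the plain lasso).
#' @export
fitAdaptiveLasso <- function(d, lambda1, weightSource = c("ols", "ridge"),
                             ridgePenalty = 1, weights = NULL,
                             control = .cdControl()) {
  d <- .asDesign(d)
  weightSource <- match.arg(weightSource)
  q <- ncol(d$X); n <- nrow(d$X)
  if (is.null(weights)) {
    if (weightSource == "ols") {
      if (q >= n)
        stop("OLS initial weights undefined for q >= n; use weightSource = 'ridge'")
      init <- qr.coef(qr(d$X), d$y)
      init[is.na(init)] <- 0
    } else {
      init <- .ridgeCoef(d$X, d$y, ridgePenalty)
    }
    weights <- ifelse(init == 0, Inf, 1 / abs(init))
  }
  if (length(weights) != q) stop("weights length must match ncol(X)")
  H <- crossprod(d$X)
  b <- crossprod(d$X, d$y)
  beta <- .cdSolveCpp(H, b, lambda1, weights, 0, numeric(q),
                      control$tol, control$maxit)
  .newFit(d, beta, lambda1, method = "adaptive-lasso")
}

#' Elastic net fit
#'
#' Minimizes \eqn{\frac12\|y-X\beta\|^2 +
#' \lambda_1\sum_j\{\frac12(1-\delta)\beta_j^2 + \delta|\beta_j|\}}, the
#' mixed L1/L2 penalty with mixing parameter \eqn{\delta \in [0,1]}
#' (\eqn{\delta = 1}: lasso, \eqn{\delta = 0}: ridge).
#'
#' @inheritParams fitLasso
#' @param delta mixing parameter in `[0, 1]`.
#' @export
fitElasticNet <- function(d, lambda1, delta, control = .cdControl()) {
  d <- .asDesign(d)
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("delta must be a single value in [0, 1]")
  if (lambda1 < 0) stop("lambda1 must be nonnegative")
  H <- crossprod(d$X)
  b <- crossprod(d$X, d$y)
  beta <- .cdSolveCpp(H, b, lambda1 * delta, rep(1, ncol(d$X)),
                      lambda1 * (1 - delta), numeric(ncol(d$X)),
                      control$tol, control$maxit)
  .newFit(d, beta, lambda1, delta = delta, method = "elastic-net")
}

#' Network-constrained lasso fit
#'
#' Minimizes \eqn{\frac12\|y-X\beta\|^2 + \lambda_1\|\beta\|_1 +
#' \lambda_2\,\tilde\beta' L \tilde\beta}, where
#' \eqn{\tilde\beta_j = s_j\beta_j} flips coefficients by a reference sign
#' vector so that negatively correlated network neighbours are smoothed
#' toward equal magnitude rather than equal signed value. With
#' \eqn{\lambda_2 = 0} or an empty graph this reduces to the lasso.
#'
#' @inheritParams fitLasso
#' @param lambda2 nonnegative Laplacian penalty weight.
#' @param L a [NormalizedLaplacian-class] (or PSD matrix) aligned with the
#'   columns of `d`.
#' @param signReference integer vector in \{-1, 0, +1\} per predictor
#'   (0 is treated as +1); typically the signs of a preliminary
#'   (stage-1 averaged) estimate. Default all +1.
#' @export
fitNetworkLasso <- function(d, lambda1, lambda2, L, signReference = NULL,
                            control = .cdControl()) {
  d <- .asDesign(d)
  q <- ncol(d$X)
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be nonnegative")
  Lm <- if (is(L, "NormalizedLaplacian")) L@matrix else as.matrix(L)
  if (nrow(Lm) != q || ncol(Lm) != q)
    stop("Laplacian dimension (", nrow(Lm), ") does not match design (", q, ")")
  ev <- eigen((Lm + t(Lm)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("Laplacian is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  Lt <- .signedLaplacian(Lm, signReference, q)
  H <- crossprod(d$X) + 2 * lambda2 * Lt
  b <- crossprod(d$X, d$y)
  beta <- .cdSolveCpp(H, b, lambda1, rep(1, q), 0, numeric(q),
                      control$tol, control$maxit)
  .newFit(d, beta, lambda1, lambda2 = lambda2, method = "network-lasso")
}

.signedLaplacian <- function(Lm, signReference, q) {
  if (is.null(signReference)) return(Lm)
  s <- as.numeric(signReference)
  if (length(s) != q) stop("signReference length must match ncol(X)")
  if (!all(s %in% c(-1, 0, 1))) stop("signReference must be in {-1, 0, +1}")
  s[s == 0] <- 1
  Lm * tcrossprod(s)
}

.ridgeCoef <- function(X, y, penalty) {
  sv <- svd(X)
  dd <- sv$d / (sv$d^2 + penalty)
  as.numeric(sv$v %*% (dd * crossprod(sv$u, y)))
}

# precomputed pieces for repeated per-response noise-variance estimates
# on a fixed design (SVD for the calibrated ridge, Gram for the lasso
# refinement)
.noisePrecompute <- function(X) {
  n <- nrow(X); q <- ncol(X)
  sv <- svd(X)
  d2 <- sv$d^2
  rank <- sum(d2 > max(d2) * 1e-12)
  dfAt <- function(lr) sum(d2 / (d2 + exp(lr)))
  rp <- exp(stats::uniroot(function(lr) dfAt(lr) - rank / 2,
                           c(log(max(d2) * 1e-12), log(max(d2) * 1e6)),
                           tol = 1e-10)$root)
  dd <- d2 / (d2 + rp)
  list(u = sv$u, dd = dd, dfEff = sum(dd), H = crossprod(X), X = X,
       n = n, q = q)
}

.noiseVarCol <- function(pre, y, refine = 3) {
  fitted <- pre$u %*% (pre$dd * crossprod(pre$u, y))
  rss <- sum((y - fitted)^2)
  s2 <- max(rss / max(pre$n - pre$dfEff, 1), 1e-12)
  if (refine > 0) {
    b <- crossprod(pre$X, y)
    yty <- sum(y^2)
    lmax <- max(abs(b), 1e-12)
    l1 <- exp(seq(log(lmax), log(lmax * 0.001), length.out = 50))
    for (i in seq_len(refine)) {
      fit <- .gridBicCpp(pre$H, b, yty, pre$n, matrix(0, pre$q, pre$q), 0,
                         l1, s2, 1e-4, 1e-7, 1e5)
      if (fit$df >= pre$n - 2) break
      s2new <- max(fit$rss / (pre$n - fit$df), 1e-12)
      if (abs(s2new - s2) < 1e-8 * s2) { s2 <- s2new; break }
      s2 <- s2new
    }
  }
  s2
}

#' Plug-in noise variance for BIC
#'
#' Residual-variance estimate used to scale the BIC's goodness-of-fit term:
#' OLS residual variance when the design is comfortably overdetermined,
#' otherwise the effective-degrees-of-freedom residual variance of a ridge
#' fit, \eqn{\hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{df}_{\mathrm{eff}})}.
#' By default the ridge penalty is calibrated (through the SVD) so that
#' \eqn{\mathrm{df}_{\mathrm{eff}}} equals half the design rank: a nearly
#' unpenalized fit would interpolate the data and report a vanishing
#' residual variance, while matching half the rank keeps enough residual
#' degrees of freedom for a stable estimate.
#'
#' The ridge stage can be badly biased when the true signal is both strong
#' and higher-dimensional than the effective df, so the estimate is refined
#' by a short fixed-point iteration: fit a BIC-tuned lasso under the
#' current \eqn{\hat\sigma^2}, re-estimate
#' \eqn{\hat\sigma^2 = \mathrm{RSS}/(n - \widehat{df})} from its residuals,
#' and repeat (3 rounds). This is the usual refitted plug-in; it is
#' deterministic given the data.
#'
#' @param d a [designData()] object.
#' @param ridgePenalty ridge penalty for the q >= n branch; `NULL` (the
#'   default) calibrates it to the half-rank effective df.
#' @param refine number of lasso refinement rounds.
#' @return positive scalar.
#' @export
estimateNoiseVariance <- function(d, ridgePenalty = NULL, refine = 3) {
  d <- .asDesign(d)
  n <- nrow(d$X); q <- ncol(d$X)
  if (q < n - 1) {
    beta <- qr.coef(qr(d$X), d$y)
    beta[is.na(beta)] <- 0
    rss <- sum((d$y - d$X %*% beta)^2)
    return(max(rss / (n - q), 1e-12))
  }
  sv <- svd(d$X)
  d2 <- sv$d^2
  if (is.null(ridgePenalty)) {
    rank <- sum(d2 > max(d2) * 1e-12)
    targetDf <- rank / 2
    dfAt <- function(lr) sum(d2 / (d2 + exp(lr)))
    lo <- log(max(d2) * 1e-12); hi <- log(max(d2) * 1e6)
    ridgePenalty <- exp(stats::uniroot(function(lr) dfAt(lr) - targetDf,
                                       c(lo, hi), tol = 1e-10)$root)
  }
  dd <- d2 / (d2 + ridgePenalty)
  fitted <- sv$u %*% (dd * crossprod(sv$u, d$y))
  rss <- sum((d$y - fitted)^2)
  dfEff <- sum(dd)
  s2 <- max(rss / max(n - dfEff, 1), 1e-12)
  if (refine > 0) {
    H <- crossprod(d$X)
    b <- crossprod(d$X, d$y)
    yty <- sum(d$y^2)
    l1 <- exp(seq(log(max(abs(b), 1e-12)), log(max(abs(b), 1e-12) * 0.001),
                  length.out = 50))
    for (i in seq_len(refine)) {
      fit <- .gridBicCpp(H, b, yty, n, matrix(0, q, q), 0, l1, s2,
                         1e-4, 1e-7, 1e5)
      if (fit$df >= n - 2) break # saturated; keep the previous estimate
      s2new <- max(fit$rss / (n - fit$df), 1e-12)
      if (abs(s2new - s2) < 1e-8 * s2) { s2 <- s2new; break }
      s2 <- s2new
    }
  }
  s2
}

#' BIC of a penalized fit
#'
#' \eqn{\mathrm{BIC} = \|y-\hat y\|^2/(n\sigma^2) + \frac{\log n}{n}
#' \widehat{df}}, with \eqn{\widehat{df}} the number of nonzero
#' coefficients.
#'
#' @param fit a `netrlFit`.
#' @param d the [designData()] the fit was computed on.
#' @param sigma2 positive noise-variance estimate
#'   (see [estimateNoiseVariance()]).
#' @return BIC score (scalar).
#' @export
bicScore <- function(fit, d, sigma2) {
  d <- .asDesign(d)
  n <- nrow(d$X)
  if (n == 0) stop("empty design")
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  r <- d$y - as.numeric(d$X %*% fit$coefficients)
  sum(r^2) / (n * sigma2) + log(n) / n * fit$df
}

#' Penalty grid
#'
#' @param lambda1 descending positive sequence, or `NULL` to derive
#'   `nlambda` log-spaced values from the data's \eqn{\lambda_{\max}} down
#'   to `minRatio` times it.
#' @param lambda2 nonnegative Laplacian penalty values.
#' @param delta elastic-net mixing values in `[0, 1]`.
#' @param nlambda,minRatio shape of the derived lambda1 sequence.
#' @return a `penaltyGrid` list.
#' @export
penaltyGrid <- function(lambda1 = NULL, lambda2 = c(0, 0.01, 0.1, 1, 10),
                        delta = seq(0.1, 0.9, by = 0.2), nlambda = 50,
                        minRatio = 0.001) {
  if (!is.null(lambda1)) {
    if (any(!is.finite(lambda1)) || any(lambda1 < 0))
      stop("lambda1 values must be finite and nonnegative")
    lambda1 <- sort(lambda1, decreasing = TRUE)
  }
  if (any(!is.finite(lambda2)) || any(lambda2 < 0))
    stop("lambda2 values must be finite and nonnegative")
  if (any(delta < 0 | delta > 1)) stop("delta values must lie in [0, 1]")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, delta = delta,
                 nlambda = nlambda, minRatio = minRatio),
            class = "penaltyGrid")
}

.lambda1Sequence <- function(grid, lambdaMax) {
  if (!is.null(grid$lambda1)) return(grid$lambda1)
  if (lambdaMax <= 0) lambdaMax <- 1e-12
  exp(seq(log(lambdaMax), log(lambdaMax * grid$minRatio),
          length.out = grid$nlambda))
}

#' BIC-driven hyperparameter selection
#'
#' Fits the requested penalized regression over every grid combination and
#' returns the fit minimizing the BIC. Ties break toward the larger
#' \eqn{\lambda_1}, then the larger \eqn{\lambda_2} (or \eqn{\delta}), i.e.
#' toward the sparser model.
#'
#' @param d a [designData()] object.
#' @param grid a [penaltyGrid()].
#' @param method one of `"lasso"`, `"adaptive-lasso"`, `"elastic-net"`,
#'   `"network-lasso"`.
#' @param sigma2 noise-variance estimate; default [estimateNoiseVariance()].
#' @param L Laplacian for `"network-lasso"`.
#' @param signReference sign reference for `"network-lasso"`.
#' @param weightSource,ridgePenalty adaptive-lasso initial estimator.
#' @param control solver control.
#' @return the best `netrlFit` (with `bic` and `sigma2` recorded).
#' @export
selectByBIC <- function(d, grid = penaltyGrid(),
                        method = c("lasso", "adaptive-lasso", "elastic-net",
                                   "network-lasso"),
                        sigma2 = NULL, L = NULL, signReference = NULL,
                        weightSource = NULL, ridgePenalty = 1,
                        control = .cdControl()) {
  d <- .asDesign(d)
  method <- match.arg(method)
  n <- nrow(d$X); q <- ncol(d$X)
  if (is.null(sigma2)) sigma2 <- estimateNoiseVariance(d)
  H <- crossprod(d$X)
  b <- crossprod(d$X, d$y)
  yty <- sum(d$y^2)

  if (method == "elastic-net") {
    if (length(grid$delta) == 0) stop("empty delta grid")
    dpos <- grid$delta[grid$delta > 0]
    # lambda_max at the smallest positive delta still zeroes the whole path
    l1 <- .lambda1Sequence(grid, max(abs(b)) /
                             (if (length(dpos)) min(dpos) else 1))
    res <- .enGridBicCpp(H, b, yty, n, l1, grid$delta, sigma2,
                         control$pathTol, control$tol, control$maxit)
    fit <- .newFit(d, res$beta, res$lambda1, delta = res$delta,
                   method = method, bic = res$bic, sigma2 = sigma2)
    return(fit)
  }

  if (method == "adaptive-lasso") {
    if (is.null(weightSource)) weightSource <- if (q < n) "ols" else "ridge"
    if (weightSource == "ols" && q >= n)
      stop("OLS initial weights undefined for q >= n; use weightSource = 'ridge'")
    init <- if (weightSource == "ols") {
      bb <- qr.coef(qr(d$X), d$y); bb[is.na(bb)] <- 0; bb
    } else .ridgeCoef(d$X, d$y, ridgePenalty)
    keep <- init != 0
    if (!any(keep)) stop("all adaptive-lasso initial weights are infinite")
    w <- 1 / abs(init[keep])
    Xs <- sweep(d$X[, keep, drop = FALSE], 2, w, "/")
    Hs <- crossprod(Xs)
    bs <- crossprod(Xs, d$y)
    l1 <- .lambda1Sequence(grid, max(abs(bs)))
    res <- .gridBicCpp(Hs, bs, yty, n, matrix(0, sum(keep), sum(keep)),
                       0, l1, sigma2, control$pathTol, control$tol,
                       control$maxit)
    beta <- numeric(q)
    beta[keep] <- res$beta / w
    return(.newFit(d, beta, res$lambda1, method = method, bic = res$bic,
                   sigma2 = sigma2))
  }

  if (method == "network-lasso") {
    if (is.null(L)) stop("network-lasso requires a Laplacian L")
    Lm <- if (is(L, "NormalizedLaplacian")) L@matrix else as.matrix(L)
    if (nrow(Lm) != q) stop("Laplacian dimension does not match design")
    Lt <- .signedLaplacian(Lm, signReference, q)
    l2 <- grid$lambda2
  } else { # lasso
    Lt <- matrix(0, q, q)
    l2 <- 0
  }
  if (length(l2) == 0) stop("empty lambda2 grid")
  l1 <- .lambda1Sequence(grid, max(abs(b)))
  res <- .gridBicCpp(H, b, yty, n, Lt, l2, l1, sigma2,
                     control$pathTol, control$tol, control$maxit)
  .newFit(d, res$beta, res$lambda1, lambda2 = res$lambda2, method = method,
          bic = res$bic, sigma2 = sigma2)
}
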