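# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: centralities are checked against an
# exhaustive shortest-path enumerator, and the penalized solvers against an
# exact sign-pattern enumeration of the convex program.

# all-pairs shortest-path counts by Floyd-Warshall on a binary adjacency
bruteShortestPathCounts <- function(A) {
  nV <- nrow(A)
  dist <- matrix(Inf, nV, nV)
  cnt <- matrix(0, nV, nV)
  for (i in seq_len(nV)) {
    dist[i, i] <- 0; cnt[i, i] <- 1
  }
  for (i in seq_len(nV)) for (j in seq_len(nV)) {
    if (i != j && A[i, j] == 1) { dist[i, j] <- 1; cnt[i, j] <- 1 }
  }
  for (k in seq_len(nV)) for (i in seq_len(nV)) for (j in seq_len(nV)) {
    if (i == j || i == k || j == k) next
    alt <- dist[i, k] + dist[k, j]
    if (alt < dist[i, j]) {
      dist[i, j] <- alt
      cnt[i, j] <- cnt[i, k] * cnt[k, j]
    } else if (is.finite(alt) && alt == dist[i, j]) {
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
    }
  }
  list(dist = dist, cnt = cnt)
}

# betweenness per the ordered-pair definition: sum over t != j != u of
# b_tu(j)/b_tu, normalized by (|V|-1)(|V|-2); disconnected pairs contribute 0
bruteBetweenness <- function(A) {
  nV <- nrow(A)
  if (nV < 3) return(rep(0, nV))
  sp <- bruteShortestPathCounts(A)
  B <- numeric(nV)
  for (j in seq_len(nV)) {
    tot <- 0
    for (t in seq_len(nV)) for (u in seq_len(nV)) {
      if (t == u || t == j || u == j) next
      if (!is.finite(sp$dist[t, u]) || sp$cnt[t, u] == 0) next
      onPath <- if (sp$dist[t, j] + sp$dist[j, u] == sp$dist[t, u])
        sp$cnt[t, j] * sp$cnt[j, u] else 0
      tot <- tot + onPath / sp$cnt[t, u]
    }
    B[j] <- tot / ((nV - 1) * (nV - 2))
  }
  B
}

# exact global minimizer of
#   0.5*||y - X b||^2 + lam1 * sum(w |b|) + lam2 * b' L b
# by enumerating all 3^q sign patterns and checking the KKT conditions of
# each candidate; valid for small q by convexity (unique objective value).
signPatternOracle <- function(X, y, lam1, w = rep(1, ncol(X)), lam2 = 0,
                              L = NULL, tol = 1e-8) {
  q <- ncol(X)
  if (is.null(L)) L <- matrix(0, q, q)
  H <- crossprod(X) + 2 * lam2 * L
  b <- crossprod(X, y)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), q)))
  best <- NULL; bestObj <- Inf
  obj <- function(beta)
    0.5 * sum((y - X %*% beta)^2) + lam1 * sum(w * abs(beta)) +
      lam2 * drop(t(beta) %*% L %*% beta)
  for (r in seq_len(nrow(patterns))) {
    s <- patterns[r, ]
    A <- which(s != 0)
    beta <- numeric(q)
    if (length(A)) {
      sol <- tryCatch(solve(H[A, A, drop = FALSE],
                            b[A] - lam1 * w[A] * s[A]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      if (any(sign(sol) != s[A])) next
      beta[A] <- sol
    }
    grad <- H %*% beta - b # gradient of the smooth part
    ok <- TRUE
    for (j in seq_len(q)) {
      if (beta[j] == 0 && abs(grad[j]) > lam1 * w[j] + tol) ok <- FALSE
    }
    if (!ok) next
    o <- obj(beta)
    if (o < bestObj) { bestObj <- o; best <- beta }
  }
  list(beta = best, objective = bestObj)
}

# random symmetric weighted graph on p nodes (possibly with isolated nodes)
randomGraph <- function(p, density = 0.5) {
  W <- matrix(0, p, p)
  up <- which(upper.tri(W))
  on <- sample(up, ceiling(density * length(up)))
  W[on] <- runif(length(on), 0.1, 2)
  W <- W + t(W)
  adjacencyFromCoefficients(W) # symmetrizes |.| form; weights already >= 0
}

# small standardized regression problem
randomDesign <- function(n, q, snr = 3) {
  X <- matrix(rnorm(n * q), n, q)
  beta <- rnorm(q) * rbinom(q, 1, 0.6)
  y <- drop(X %*% beta) + rnorm(n, sd = 1 / snr * max(sqrt(sum(beta^2)), 1))
  designData(X, y)
}
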