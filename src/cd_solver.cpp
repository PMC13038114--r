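#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coordinate descent for penalized quadratic programs in Gram form:
//
//   f(beta) = 0.5 * beta' (H + a I) beta - b' beta + lam * sum_j w_j |beta_j|
//
// With H = X'X and b = X'y this is 0.5*||y - X beta||^2 + penalty up to a
// constant, so the same routine serves the lasso (w = 1, a = 0), the adaptive
// lasso (w = 1/|beta_init|), the elastic net (a = lambda1*(1-delta),
// lam = lambda1*delta), and the network-constrained lasso
// (H = X'X + 2*lambda2*Ltilde). Non-finite weights freeze a coordinate at 0.

static inline double soft_thresh(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One CD sweep over the coordinates listed in `idx`; returns max |change|.
static double cd_sweep(const mat& H, const vec& b, double lam, const vec& w,
                       double diag_add, vec& beta, vec& hbeta,
                       const uvec& idx) {
  const uword q = b.n_elem;
  double delta_max = 0.0;
  double* hb = hbeta.memptr();
  for (uword t = 0; t < idx.n_elem; ++t) {
    const uword j = idx(t);
    const double* hc = H.colptr(j);
    if (!std::isfinite(w(j))) { // excluded predictor
      if (beta(j) != 0.0) {
        const double d0 = beta(j);
        for (uword r = 0; r < q; ++r) hb[r] -= hc[r] * d0;
        beta(j) = 0.0;
      }
      continue;
    }
    const double hjj = hc[j] + diag_add;
    if (hjj <= 0.0) continue;
    // partial residual gradient with coordinate j removed
    const double zj = b(j) - (hb[j] - hc[j] * beta(j));
    const double bj = soft_thresh(zj, lam * w(j)) / hjj;
    const double d = bj - beta(j);
    if (d != 0.0) {
      for (uword r = 0; r < q; ++r) hb[r] += hc[r] * d;
      beta(j) = bj;
      const double ad = std::fabs(d);
      if (ad > delta_max) delta_max = ad;
    }
  }
  return delta_max;
}

// f(beta) given the cached hbeta = H*beta (penalty skips zero coords, so
// infinite weights on excluded predictors contribute nothing)
static double cd_objective(const vec& beta, const vec& hbeta, const vec& b,
                           double lam, const vec& w, double diag_add) {
  double pen = 0.0;
  for (uword j = 0; j < beta.n_elem; ++j)
    if (beta(j) != 0.0) pen += w(j) * std::fabs(beta(j));
  return 0.5 * dot(beta, hbeta) + 0.5 * diag_add * dot(beta, beta) -
         dot(b, beta) + lam * pen;
}

// Newton acceleration on the current active set: solve the
// sign-restricted KKT system (H_AA + a I) x = b_A - lam * w_A .* sign,
// then take the longest sign-respecting step toward x (coordinates that
// would cross zero are removed exactly). Accepted only if the objective
// decreases; near-singular active blocks get a negligible ridge jitter so
// the solve is defined on rank-deficient bootstrap designs.
static bool newton_step(const mat& H, const vec& b, double lam, const vec& w,
                        double diag_add, vec& beta, vec& hbeta) {
  const uvec A = find(beta != 0.0);
  if (A.n_elem == 0) return false;
  const vec betaA = beta(A);
  const vec s = sign(betaA);
  mat HA = H.submat(A, A);
  HA.diag() += diag_add + 1e-9 * (trace(HA) / A.n_elem + 1.0);
  vec x;
  if (!solve(x, HA, b(A) - lam * (w(A) % s),
             solve_opts::likely_sympd + solve_opts::no_approx))
    return false;
  const vec d = x - betaA;
  double t = 1.0;
  for (uword j = 0; j < A.n_elem; ++j)
    if (x(j) * s(j) < 0.0) // crosses zero along the segment
      t = std::min(t, betaA(j) / (betaA(j) - x(j)));
  if (!(t > 0.0)) return false;
  vec newA = betaA + t * d;
  for (uword j = 0; j < A.n_elem; ++j)
    if (newA(j) * s(j) <= 0.0) newA(j) = 0.0;
  const double f0 = cd_objective(beta, hbeta, b, lam, w, diag_add);
  const vec hnew = hbeta + H.cols(A) * (newA - betaA);
  vec nbeta = beta;
  nbeta(A) = newA;
  if (cd_objective(nbeta, hnew, b, lam, w, diag_add) >= f0 - 1e-12)
    return false;
  beta = nbeta;
  hbeta = hnew;
  return true;
}

// In-place CD with active-set iteration and Newton acceleration; hbeta
// caches H*beta throughout. Convergence on max |coef change| < tol.
// full sweep without an index vector (no allocations; small-q fast path)
static double cd_sweep_all(const mat& H, const vec& b, double lam,
                           const vec& w, double diag_add, vec& beta,
                           vec& hbeta) {
  const uword q = b.n_elem;
  double delta_max = 0.0;
  double* hb = hbeta.memptr();
  for (uword j = 0; j < q; ++j) {
    const double* hc = H.colptr(j);
    if (!std::isfinite(w(j))) {
      if (beta(j) != 0.0) {
        const double d0 = beta(j);
        for (uword r = 0; r < q; ++r) hb[r] -= hc[r] * d0;
        beta(j) = 0.0;
      }
      continue;
    }
    const double hjj = hc[j] + diag_add;
    if (hjj <= 0.0) continue;
    const double zj = b(j) - (hb[j] - hc[j] * beta(j));
    const double bj = soft_thresh(zj, lam * w(j)) / hjj;
    const double d = bj - beta(j);
    if (d != 0.0) {
      for (uword r = 0; r < q; ++r) hb[r] += hc[r] * d;
      beta(j) = bj;
      const double ad = std::fabs(d);
      if (ad > delta_max) delta_max = ad;
    }
  }
  return delta_max;
}

static void cd_core(const mat& H, const vec& b, double lam, const vec& w,
                    double diag_add, vec& beta, vec& hbeta,
                    double tol, int maxit) {
  const uword q = b.n_elem;
  if (q <= 16) { // active-set bookkeeping costs more than the sweeps
    for (int it = 0; it < maxit; ++it)
      if (cd_sweep_all(H, b, lam, w, diag_add, beta, hbeta) < tol) break;
    return;
  }
  const uvec all = regspace<uvec>(0, q - 1);
  int it = 0;
  while (it < maxit) {
    ++it;
    if (cd_sweep(H, b, lam, w, diag_add, beta, hbeta, all) < tol) break;
    while (it < maxit) {
      const uvec active = find(beta != 0.0);
      if (active.n_elem == 0) break;
      double d = 1.0;
      for (int k = 0; k < 4 && it < maxit; ++k) {
        ++it;
        d = cd_sweep(H, b, lam, w, diag_add, beta, hbeta, active);
        if (d < tol) break;
      }
      if (d < tol) break; // confirm with a full sweep in the outer loop
      // Newton pays off only when the active block is large enough for
      // CD zigzag to be the bottleneck
      if (active.n_elem >= 20) {
        ++it;
        newton_step(H, b, lam, w, diag_add, beta, hbeta);
      }
    }
  }
}

// [[Rcpp::export(name = ".cdSolveCpp")]]
arma::vec cd_solve_cpp(const arma::mat& H, const arma::vec& b, double lam,
                       const arma::vec& w, double diag_add,
                       const arma::vec& beta0, double tol, int maxit) {
  vec beta = beta0;
  vec hbeta = H * beta;
  cd_core(H, b, lam, w, diag_add, beta, hbeta, tol, maxit);
  return beta;
}

struct GridFit {
  vec beta;
  double lambda1 = 0.0, lambda2 = 0.0, bic = datum::inf, rss = 0.0;
  int df = 0;
};

// BIC = rss / (n * sigma2) + log(n)/n * df,  df = #nonzero.
static double bic_score(double rss, int df, int n, double sigma2) {
  return rss / (static_cast<double>(n) * sigma2) +
         std::log(static_cast<double>(n)) / static_cast<double>(n) * df;
}

// Select the (lambda1, lambda2) grid combination minimizing BIC.
// Hs[k] = XtX + 2*lambda2[k]*Lsub is the quadratic matrix for lambda2[k].
// Ties break toward larger lambda1, then larger lambda2 (sparser model):
// candidates are visited in that priority order and replaced only on a
// strict improvement.
// The lambda1 path is scanned at the coarser `path_tol`; the selected
// model is then polished at the full `tol`. Because df is non-increasing
// in lambda1, a path is abandoned as soon as the BIC's complexity term
// alone, log(n)/n * df, exceeds the best BIC seen so far: no later (denser)
// point on that path can win. This prunes the saturated small-lambda tail.
static GridFit grid_bic_select(const mat& XtX, const vec& b, double yty, int n,
                               const std::vector<mat>& Hs, const vec& l2vals,
                               const vec& l1vals, double sigma2,
                               double path_tol, double tol, int maxit) {
  const uword q = b.n_elem;
  const uword n1 = l1vals.n_elem, n2 = l2vals.n_elem;
  const vec w = ones<vec>(q);
  const double logn_n = std::log(static_cast<double>(n)) /
                        static_cast<double>(n);
  // the scan tolerance is relative to the response scale; the polish below
  // is at the absolute tolerance
  const double scan_tol =
      path_tol * std::max(1.0, std::sqrt(yty / std::max(n, 1)));
  const int scan_maxit = std::min(maxit, 300);
  // cap the polish sweeps: on rank-deficient designs the minimizer is not
  // unique and CD wanders within the solution set long after the objective
  // has converged
  const int polish_maxit = std::min(maxit, 3000);

  // streaming minimum with the tie rule made explicit: on an exact BIC
  // tie the larger lambda1 wins, then the larger lambda2
  GridFit best;
  vec best_beta(q, fill::zeros);
  uword best_k = 0;
  double best_seen = datum::inf;
  vec beta(q), hbeta(q);

  // lambda1 values are expected in descending order (warm-started path)
  for (uword k = 0; k < n2; ++k) {
    beta.zeros();
    hbeta.zeros();
    for (uword i = 0; i < n1; ++i) {
      cd_core(Hs[k], b, l1vals(i), w, 0.0, beta, hbeta, scan_tol, scan_maxit);
      // rss = yty - 2 b'beta + beta' XtX beta, exploiting sparsity
      double lin = 0.0, quad = 0.0;
      int df = 0;
      for (uword j = 0; j < q; ++j) {
        if (beta(j) == 0.0) continue;
        ++df;
        lin += b(j) * beta(j);
        const double* col = XtX.colptr(j);
        double acc = 0.0;
        for (uword r = 0; r < q; ++r) acc += col[r] * beta(r);
        quad += acc * beta(j);
      }
      const double rss = std::max(yty - 2.0 * lin + quad, 0.0);
      const double bic = bic_score(rss, df, n, sigma2);
      const bool better =
          bic < best.bic ||
          (bic == best.bic &&
           (l1vals(i) > best.lambda1 ||
            (l1vals(i) == best.lambda1 && l2vals(k) > best.lambda2)));
      if (better) {
        best.bic = bic;
        best.lambda1 = l1vals(i);
        best.lambda2 = l2vals(k);
        best_beta = beta;
        best_k = k;
      }
      if (bic < best_seen) best_seen = bic;
      if (logn_n * df > best_seen) break;
    }
  }
  // polish the winner at the full tolerance
  vec bb = best_beta;
  if (std::isfinite(best.bic)) {
    vec hb2 = Hs[best_k] * bb;
    cd_core(Hs[best_k], b, best.lambda1, w, 0.0, bb, hb2, tol, polish_maxit);
  }
  best.beta = bb;
  best.rss = std::max(yty - 2.0 * dot(bb, b) + dot(bb, XtX * bb), 0.0);
  best.df = static_cast<int>(accu(bb != 0.0));
  best.bic = bic_score(best.rss, best.df, n, sigma2);
  return best;
}

static vec lambda_sequence(double lmax, int nlambda, double min_ratio) {
  if (lmax <= 0.0) lmax = 1e-12;
  return exp(linspace<vec>(std::log(lmax), std::log(lmax * min_ratio),
                           nlambda));
}

// [[Rcpp::export(name = ".gridBicCpp")]]
Rcpp::List grid_bic_cpp(const arma::mat& XtX, const arma::vec& Xty, double yty,
                        int n, const arma::mat& Lsub, const arma::vec& lambda2,
                        const arma::vec& lambda1, double sigma2,
                        double path_tol, double tol, int maxit) {
  std::vector<mat> Hs;
  for (uword k = 0; k < lambda2.n_elem; ++k)
    Hs.push_back(XtX + 2.0 * lambda2(k) * Lsub);
  GridFit g = grid_bic_select(XtX, Xty, yty, n, Hs, lambda2, lambda1, sigma2,
                              path_tol, tol, maxit);
  return Rcpp::List::create(
      Rcpp::Named("beta") = g.beta, Rcpp::Named("lambda1") = g.lambda1,
      Rcpp::Named("lambda2") = g.lambda2, Rcpp::Named("bic") = g.bic,
      Rcpp::Named("rss") = g.rss, Rcpp::Named("df") = g.df);
}

// Stage-1 ensemble: for each bootstrap replicate, fit a BIC-tuned lasso on
// the drawn rows and uniformly drawn candidate predictors. Returns the p x
// Omega coefficient matrix (zeros outside each replicate's candidate set).
// [[Rcpp::export(name = ".stage1EnsembleCpp")]]
arma::mat stage1_ensemble_cpp(const arma::mat& X, const arma::vec& y,
                              const arma::umat& rows, const arma::umat& cands,
                              int nlambda, double min_ratio, double sigma2,
                              double path_tol, double tol, int maxit) {
  const uword p = X.n_cols, Omega = rows.n_cols;
  mat coefs(p, Omega, fill::zeros);
  const vec l2(1, fill::zeros);
  for (uword w = 0; w < Omega; ++w) {
    const uvec r = rows.col(w), cs = cands.col(w);
    const mat Xs = X.submat(r, cs);
    const vec ys = y(r);
    const mat XtX = Xs.t() * Xs;
    const vec b = Xs.t() * ys;
    const double yty = dot(ys, ys);
    const double lmax = b.n_elem ? abs(b).max() : 0.0;
    if (lmax <= 0.0) continue;
    const vec l1 = lambda_sequence(lmax, nlambda, min_ratio);
    std::vector<mat> Hs(1, XtX);
    GridFit g = grid_bic_select(XtX, b, yty, static_cast<int>(r.n_elem), Hs,
                                l2, l1, sigma2, path_tol, tol, maxit);
    for (uword j = 0; j < cs.n_elem; ++j) coefs(cs(j), w) = g.beta(j);
  }
  return coefs;
}

// Stage-2 ensemble with shared candidate/row streams across response
// columns. Y holds the observed target in column 0 and (for the permutation
// test) the permuted targets in the remaining columns; only the response
// changes across columns, so the per-replicate Gram and Laplacian blocks are
// reused. Returns the observed-column coefficients, the nonzero-selection
// counts m (p x ncol(Y)), and each gene's candidacy count.
// [[Rcpp::export(name = ".stage2EnsembleCpp")]]
Rcpp::List stage2_ensemble_cpp(const arma::mat& X, const arma::mat& Y,
                               const arma::umat& rows, const arma::umat& cands,
                               const arma::mat& Ltilde,
                               const arma::vec& lambda2, int nlambda,
                               double min_ratio, const arma::vec& sigma2,
                               double path_tol, double tol, int maxit) {
  const uword p = X.n_cols, Omega = rows.n_cols, C = Y.n_cols;
  const int nb = static_cast<int>(rows.n_rows);
  mat coefs(p, Omega, fill::zeros);
  umat m(p, C, fill::zeros);
  uvec cand_count(p, fill::zeros);

  for (uword w = 0; w < Omega; ++w) {
    const uvec r = rows.col(w), cs = cands.col(w);
    for (uword j = 0; j < cs.n_elem; ++j) cand_count(cs(j)) += 1;
    const mat Xs = X.submat(r, cs);
    const mat XtX = Xs.t() * Xs;
    const mat Lsub = Ltilde.submat(cs, cs);
    std::vector<mat> Hs;
    for (uword k = 0; k < lambda2.n_elem; ++k)
      Hs.push_back(XtX + 2.0 * lambda2(k) * Lsub);
    for (uword c = 0; c < C; ++c) {
      const vec yc = Y.col(c);
      const vec ys = yc(r);
      const vec b = Xs.t() * ys;
      const double yty = dot(ys, ys);
      const double lmax = b.n_elem ? abs(b).max() : 0.0;
      if (lmax <= 0.0) continue;
      const vec l1 = lambda_sequence(lmax, nlambda, min_ratio);
      const double s2 = sigma2.n_elem == 1 ? sigma2(0) : sigma2(c);
      GridFit g = grid_bic_select(XtX, b, yty, nb, Hs, lambda2, l1, s2,
                                  path_tol, tol, maxit);
      for (uword j = 0; j < cs.n_elem; ++j) {
        if (g.beta(j) != 0.0) {
          m(cs(j), c) += 1;
          if (c == 0) coefs(cs(j), w) = g.beta(j);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("coefficients") = coefs,
                            Rcpp::Named("m") = m,
                            Rcpp::Named("candCount") = cand_count);
}

// Elastic-net grid: penalty lambda1 * (0.5*(1-delta)*beta^2 + delta*|beta|).
// Warm-started descending-lambda1 path per delta, with the same BIC-based
// path pruning and winner polish as the Laplacian grid. Ties break toward
// larger lambda1, then larger delta.
// [[Rcpp::export(name = ".enGridBicCpp")]]
Rcpp::List en_grid_bic_cpp(const arma::mat& XtX, const arma::vec& Xty,
                           double yty, int n, const arma::vec& lambda1,
                           const arma::vec& delta, double sigma2,
                           double path_tol, double tol, int maxit) {
  const uword q = Xty.n_elem;
  const uword n1 = lambda1.n_elem, nd = delta.n_elem;
  const vec w = ones<vec>(q);
  const double logn_n = std::log(static_cast<double>(n)) /
                        static_cast<double>(n);
  const double scan_tol =
      path_tol * std::max(1.0, std::sqrt(yty / std::max(n, 1)));
  const int scan_maxit = std::min(maxit, 300);
  const int polish_maxit = std::min(maxit, 3000);
  cube betas(q, n1, nd, fill::zeros);
  mat bics(n1, nd, fill::value(datum::inf));
  double best_seen = datum::inf;

  for (uword k = 0; k < nd; ++k) {
    vec beta(q, fill::zeros), hbeta(q, fill::zeros);
    for (uword i = 0; i < n1; ++i) { // descending lambda1, warm start
      // hbeta caches XtX*beta only; the ridge part enters via diag_add
      cd_core(XtX, Xty, lambda1(i) * delta(k), w,
              lambda1(i) * (1.0 - delta(k)), beta, hbeta, scan_tol,
              scan_maxit);
      betas.slice(k).col(i) = beta;
      const double rss =
          std::max(yty - 2.0 * dot(beta, Xty) + dot(beta, XtX * beta), 0.0);
      const int df = static_cast<int>(accu(beta != 0.0));
      bics(i, k) = bic_score(rss, df, n, sigma2);
      if (bics(i, k) < best_seen) best_seen = bics(i, k);
      if (delta(k) > 0.0 && logn_n * df > best_seen) break;
    }
  }

  uvec ordd = sort_index(delta, "descend");
  GridFit best;
  double best_delta = NA_REAL;
  uword bi = 0, bk = 0;
  for (uword i = 0; i < n1; ++i) {
    for (uword kk = 0; kk < nd; ++kk) {
      const uword k = ordd(kk);
      if (bics(i, k) < best.bic) {
        best.bic = bics(i, k);
        best.lambda1 = lambda1(i);
        best_delta = delta(k);
        bi = i; bk = k;
      }
    }
  }
  vec beta = betas.slice(bk).col(bi);
  if (std::isfinite(best.bic)) {
    vec hbeta = XtX * beta;
    cd_core(XtX, Xty, best.lambda1 * best_delta, w,
            best.lambda1 * (1.0 - best_delta), beta, hbeta, tol,
            polish_maxit);
  }
  best.beta = beta;
  best.rss = std::max(yty - 2.0 * dot(beta, Xty) + dot(beta, XtX * beta), 0.0);
  best.df = static_cast<int>(accu(beta != 0.0));
  best.bic = bic_score(best.rss, best.df, n, sigma2);
  return Rcpp::List::create(
      Rcpp::Named("beta") = best.beta, Rcpp::Named("lambda1") = best.lambda1,
      Rcpp::Named("delta") = best_delta, Rcpp::Named("bic") = best.bic,
      Rcpp::Named("rss") = best.rss, Rcpp::Named("df") = best.df);
}
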