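// Computational kernels: dense phase-1 simplex for separation detection,
// Firth-penalized and ML logistic scoring, batch samplers for the three
// randomization procedures, and batch evaluation of the two max-contrast
// randomization-test statistics.
#define ARMA_WARN_LEVEL 0  // near-singular systems are handled by fallbacks
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Phase-1 simplex (Bland's rule) for LP feasibility
// ---------------------------------------------------------------------------

// Bland pivoting on tableau T (m x (ncols+1), last column = rhs), basis[i] is
// the column currently basic in row i.  cost has length ncols.  Returns 0 on
// optimality, 1 if unbounded, 2 if the iteration cap was hit.
static int simplex_core(arma::mat& T, std::vector<int>& basis,
                        const arma::rowvec& cost, int ncols, double tol) {
  const int m = T.n_rows;
  arma::vec cB(m);
  for (int iter = 0; iter < 50000; ++iter) {
    for (int i = 0; i < m; ++i) cB(i) = cost(basis[i]);
    int enter = -1;
    for (int j = 0; j < ncols; ++j) {
      double d = cost(j) - arma::dot(cB, T.col(j));
      if (d < -tol) { enter = j; break; }  // Bland: smallest eligible index
    }
    if (enter < 0) return 0;
    int leave = -1; double best = 0.0;
    for (int i = 0; i < m; ++i) {
      double a = T(i, enter);
      if (a > tol) {
        double ratio = T(i, ncols) / a;
        if (leave < 0 || ratio < best - 1e-12 ||
            (std::abs(ratio - best) <= 1e-12 && basis[i] < basis[leave])) {
          leave = i; best = ratio;
        }
      }
    }
    if (leave < 0) return 1;
    double piv = T(leave, enter);
    T.row(leave) /= piv;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = T(i, enter);
      if (f != 0.0) T.row(i) -= f * T.row(leave);
    }
    basis[leave] = enter;
  }
  return 2;
}

// Feasibility of { b free : A b >= e } via phase-1 on A(u-v) - s = e, all >= 0.
static bool margin_feasible(const arma::mat& A, const arma::vec& e) {
  const int m = A.n_rows, p = A.n_cols;
  const int nvar = 2 * p + m;          // u, v, surplus
  arma::mat T(m, nvar + m + 1, arma::fill::zeros);
  T.cols(0, p - 1) = A;
  T.cols(p, 2 * p - 1) = -A;
  for (int i = 0; i < m; ++i) {
    T(i, 2 * p + i) = -1.0;            // surplus
    T(i, nvar + i) = 1.0;              // artificial
    T(i, nvar + m) = e(i);             // rhs (>= 0)
  }
  arma::rowvec cost(nvar + m, arma::fill::zeros);
  cost.cols(nvar, nvar + m - 1).fill(1.0);
  std::vector<int> basis(m);
  for (int i = 0; i < m; ++i) basis[i] = nvar + i;
  arma::mat Twork = T;
  int status = simplex_core(Twork, basis, cost, nvar + m, 1e-9);
  if (status != 0) return false;
  double obj = 0.0;
  for (int i = 0; i < m; ++i)
    if (basis[i] >= nvar) obj += Twork(i, nvar + m);
  return obj < 1e-7;
}

// Separation classifier for a binary design with full-column-rank X.
// Rows of the signed design A = (2y-1) * x.  Complete separation: exists b
// with A b >= 1 (strict inequalities are scale-invariant).  Any separation
// (complete or quasicomplete): exists b != 0 with A b >= 0; with full rank
// this is equivalent (by rescaling) to feasibility of {A b >= 0, 1'A b >= 1}.
// 0 = none, 1 = quasicomplete, 2 = complete.
// [[Rcpp::export]]
int separation_lp_cpp(const arma::mat& X, const arma::ivec& y,
                      bool complete_only) {
  const int n = X.n_rows;
  arma::mat A = X;
  for (int i = 0; i < n; ++i)
    if (y(i) == 0) A.row(i) *= -1.0;
  arma::vec ones(n, arma::fill::ones);
  if (margin_feasible(A, ones)) return 2;
  if (complete_only) return 0;
  arma::mat A2 = arma::join_cols(A, arma::sum(A, 0));
  arma::vec e(n + 1, arma::fill::zeros);
  e(n) = 1.0;
  return margin_feasible(A2, e) ? 1 : 0;
}

// Non-existence of the MLE for one coefficient: the logistic MLE of
// coefficient j is infinite iff the cone of directions of recession
// {b : A b >= 0} contains a direction with b_j != 0; by rescaling this is
// the feasibility of {A b >= 0, b_j >= 1} or {A b >= 0, -b_j >= 1}.
// [[Rcpp::export]]
bool coef_mle_infinite_cpp(const arma::mat& X, const arma::ivec& y, int j) {
  const int n = X.n_rows, p = X.n_cols;
  arma::mat A = X;
  for (int i = 0; i < n; ++i)
    if (y(i) == 0) A.row(i) *= -1.0;
  arma::rowvec ej(p, arma::fill::zeros);
  ej(j) = 1.0;
  arma::vec e(n + 1, arma::fill::zeros);
  e(n) = 1.0;
  if (margin_feasible(arma::join_cols(A, ej), e)) return true;
  return margin_feasible(arma::join_cols(A, -ej), e);
}

// ---------------------------------------------------------------------------
// Logistic regression: ML scoring and Firth-penalized scoring
// ---------------------------------------------------------------------------

static inline double softplus(double eta) {
  return (eta > 30.0) ? eta : std::log1p(std::exp(eta));
}

static arma::mat safe_inv_sympd(const arma::mat& M) {
  arma::mat V;
  if (!arma::inv_sympd(V, M)) V = arma::pinv(M);
  return V;
}

// Plain IRLS maximum likelihood, mirroring glm.fit for the binomial/logit
// family: mustart = (y + 1/2)/2, weighted-least-squares updates, relative
// deviance convergence (1e-8), maxit 25.  Under separation the estimates
// drift; the last iterate is returned as-is with converged = FALSE,
// matching the behavior of standard software.
// [[Rcpp::export]]
List irls_fit_cpp(const arma::mat& X, const arma::vec& y,
                  int maxit = 25, double tol = 1e-8) {
  const int p = X.n_cols;
  const int n = X.n_rows;
  arma::vec mu = (y + 0.5) / 2.0;
  arma::vec eta = arma::log(mu / (1.0 - mu));
  arma::vec beta(p, arma::fill::zeros);
  double dev_old = R_PosInf;
  bool converged = false;
  arma::mat info(p, p, arma::fill::eye);
  for (int it = 0; it < maxit; ++it) {
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return (v < 1e-12) ? 1e-12 : v; });
    arma::vec z = eta + (y - mu) / w;
    info = X.t() * (X.each_col() % w);
    arma::vec rhs = X.t() * (w % z);
    if (!arma::solve(beta, info, rhs, arma::solve_opts::likely_sympd))
      beta = arma::pinv(info) * rhs;
    eta = X * beta;
    mu = 1.0 / (1.0 + arma::exp(-eta));
    double dev = 0.0;
    for (int i = 0; i < n; ++i)
      dev += 2.0 * (softplus(eta(i)) - y(i) * eta(i));
    if (std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) {
      converged = true; break;
    }
    dev_old = dev;
  }
  // vcov from the information of the last weighted solve, as glm.fit does
  return List::create(_["coefficients"] = beta,
                      _["vcov"] = safe_inv_sympd(info),
                      _["converged"] = converged);
}

// Firth-penalized scoring with step-halving on the penalized log-likelihood
// l(beta) + 0.5 log|I(beta)|.  Estimates exist and are finite for every
// binary dataset.  Covariance = inverse penalized information at the optimum.
// [[Rcpp::export]]
List firth_fit_cpp(const arma::mat& X, const arma::vec& y,
                   int maxit = 100, double score_tol = 1e-6,
                   double step_tol = 1e-8,
                   Nullable<NumericVector> start = R_NilValue) {
  const int p = X.n_cols;
  const int n = X.n_rows;
  arma::vec beta(p, arma::fill::zeros);
  if (start.isNotNull()) {
    NumericVector s(start);
    if ((int)s.size() == p) beta = as<arma::vec>(s);
  }

  // penalized log-likelihood; info_out is X'WX, ldet its log-determinant
  auto pll = [&](const arma::vec& b, arma::mat& info_out) -> double {
    arma::vec eta = X * b;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    info_out = X.t() * (X.each_col() % w);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) ll += y(i) * eta(i) - softplus(eta(i));
    arma::mat R;
    double ldet;
    if (arma::chol(R, info_out)) {
      ldet = 2.0 * arma::sum(arma::log(R.diag()));
    } else {
      double sign;
      arma::log_det(ldet, sign, info_out);
    }
    return ll + 0.5 * ldet;
  };

  arma::mat info(p, p);
  double f_cur = pll(beta, info);
  bool converged = false;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    info = X.t() * (X.each_col() % w);
    arma::mat V = safe_inv_sympd(info);
    // hat diagonal of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
    arma::vec h = arma::sum((X * V) % X, 1) % w;
    arma::vec ustar = X.t() * (y - mu + h % (0.5 - mu));
    arma::vec step = V * ustar;
    double f_new = 0.0;
    arma::mat info_new;
    arma::vec beta_new;
    double fac = 1.0;
    bool improved = false;
    for (int half = 0; half < 25; ++half) {
      beta_new = beta + fac * step;
      f_new = pll(beta_new, info_new);
      if (std::isfinite(f_new) && f_new >= f_cur - 1e-12) { improved = true; break; }
      fac *= 0.5;
    }
    if (!improved) { beta_new = beta; f_new = f_cur; info_new = info; }
    double max_step = arma::abs(beta_new - beta).max();
    beta = beta_new; f_cur = f_new; info = info_new;
    if (arma::abs(ustar).max() < score_tol && max_step < step_tol) {
      converged = true; break;
    }
  }
  return List::create(_["coefficients"] = beta,
                      _["vcov"] = safe_inv_sympd(info),
                      _["converged"] = converged,
                      _["logLikPenalized"] = f_cur);
}

// ---------------------------------------------------------------------------
// Batch samplers (arm labels 1..k); all draws use R's RNG stream
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix sample_cr_cpp(int ndraw, int n, int k) {
  IntegerMatrix Z(ndraw, n);
  for (int d = 0; d < ndraw; ++d)
    for (int i = 0; i < n; ++i) {
      int a = 1 + (int)std::floor(unif_rand() * k);
      if (a > k) a = k;
      Z(d, i) = a;
    }
  return Z;
}

static void shuffle_segment(std::vector<int>& v, int from, int to) {
  for (int i = to - from - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[from + i], v[from + j]);
  }
}

// [[Rcpp::export]]
IntegerMatrix sample_ra_cpp(int ndraw, const IntegerVector& targets) {
  int k = targets.size(), n = 0;
  for (int j = 0; j < k; ++j) n += targets[j];
  std::vector<int> urn;
  urn.reserve(n);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < targets[j]; ++c) urn.push_back(j + 1);
  IntegerMatrix Z(ndraw, n);
  std::vector<int> v(n);
  for (int d = 0; d < ndraw; ++d) {
    v = urn;
    shuffle_segment(v, 0, n);
    for (int i = 0; i < n; ++i) Z(d, i) = v[i];
  }
  return Z;
}

// [[Rcpp::export]]
IntegerMatrix sample_pbd_cpp(int ndraw, const IntegerVector& block_comp,
                             int nblocks) {
  int k = block_comp.size(), m = 0;
  for (int j = 0; j < k; ++j) m += block_comp[j];
  int n = m * nblocks;
  std::vector<int> block;
  block.reserve(m);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < block_comp[j]; ++c) block.push_back(j + 1);
  IntegerMatrix Z(ndraw, n);
  std::vector<int> v(m);
  for (int d = 0; d < ndraw; ++d)
    for (int b = 0; b < nblocks; ++b) {
      v = block;
      shuffle_segment(v, 0, m);
      for (int i = 0; i < m; ++i) Z(d, b * m + i) = v[i];
    }
  return Z;
}

// ---------------------------------------------------------------------------
// Optimal contrasts and max-contrast statistics
// ---------------------------------------------------------------------------

// Optimal contrast for standardized shape means mu0 (length ka) under group
// mean covariance S: c proportional to S^{-1}(mu0 - 1 (1'S^{-1}mu0)/(1'S^{-1}1)),
// unit norm, oriented so that c'mu0 > 0.  Returns false for degenerate
// (constant) shapes.
static bool contrast_from_cov(const arma::vec& mu0, const arma::mat& S,
                              arma::vec& c_out) {
  const int ka = mu0.n_elem;
  if (mu0.max() - mu0.min() < 1e-12) return false;
  arma::vec ones(ka, arma::fill::ones);
  arma::mat rhs(ka, 2);
  rhs.col(0) = mu0; rhs.col(1) = ones;
  arma::mat sol;
  if (!arma::solve(sol, S, rhs, arma::solve_opts::likely_sympd))
    sol = arma::pinv(S) * rhs;
  arma::vec Sim = sol.col(0), Si1 = sol.col(1);
  double denom = arma::dot(ones, Si1);
  arma::vec c = Sim - Si1 * (arma::dot(ones, Sim) / denom);
  double nrm = arma::norm(c, 2);
  if (nrm < 1e-14) return false;
  c /= nrm;
  if (arma::dot(c, mu0) < 0) c = -c;
  c_out = c;
  return true;
}

// Exposed for the contrasts module (and tested against a brute-force oracle).
// [[Rcpp::export]]
arma::mat optimal_contrasts_cpp(const arma::mat& mu0, const arma::mat& S) {
  const int k = mu0.n_rows, M = mu0.n_cols;
  arma::mat C(k, M, arma::fill::zeros);
  for (int m = 0; m < M; ++m) {
    arma::vec c;
    if (!contrast_from_cov(mu0.col(m), S, c))
      stop("degenerate (constant) candidate shape: no contrast exists");
    C.col(m) = c;
  }
  return C;
}

// Model-based statistic S1 for a batch of assignment sequences.
// Z: ndraw x n with labels 1..k; y: outcomes; X: n x p covariates (p may be 0);
// mu0: k x M standardized candidate means; family 0 = binomial, 1 = gaussian;
// method 0 = ML, 1 = Firth (ignored for gaussian); recompute: re-derive
// contrasts from each draw's estimated covariance (otherwise Cfix is used
// whenever all k arms are present).
// [[Rcpp::export]]
arma::vec s1_stat_batch_cpp(const arma::imat& Z, const arma::vec& y,
                            const arma::mat& X, const arma::mat& mu0,
                            int family, int method, bool recompute,
                            const arma::mat& Cfix) {
  const int ndraw = Z.n_rows, n = Z.n_cols;
  const int k = mu0.n_rows, M = mu0.n_cols;
  const int p = X.n_cols;
  arma::vec out(ndraw);
  arma::rowvec xbar = (p > 0) ? arma::mean(X, 0) : arma::rowvec();
  arma::vec warm;            // observed-sequence Firth solution, reused as
  bool warm_ok = false;      // a warm start for the re-randomization refits

  for (int d = 0; d < ndraw; ++d) {
    arma::ivec counts(k, arma::fill::zeros);
    for (int i = 0; i < n; ++i) counts(Z(d, i) - 1)++;
    arma::uvec active = arma::find(counts > 0);
    const int ka = active.n_elem;
    if (ka < 2) { out(d) = 0.0; continue; }
    arma::ivec pos(k); pos.fill(-1);
    for (int a = 0; a < ka; ++a) pos(active(a)) = a;

    arma::mat D(n, ka + p, arma::fill::zeros);
    for (int i = 0; i < n; ++i) D(i, pos(Z(d, i) - 1)) = 1.0;
    if (p > 0) D.cols(ka, ka + p - 1) = X;

    arma::vec beta;
    arma::mat V;
    if (family == 1) {          // gaussian: least squares
      arma::mat XtX = D.t() * D;
      arma::vec Xty = D.t() * y;
      if (!arma::solve(beta, XtX, Xty, arma::solve_opts::likely_sympd))
        beta = arma::pinv(XtX) * Xty;
      arma::vec res = y - D * beta;
      double s2 = arma::dot(res, res) / std::max(1, n - ka - p);
      V = s2 * safe_inv_sympd(XtX);
    } else if (method == 1) {   // binomial Firth
      List f = (warm_ok && ka == k)
        ? firth_fit_cpp(D, y, 100, 1e-6, 1e-8, wrap(warm))
        : firth_fit_cpp(D, y, 100, 1e-6, 1e-8);
      beta = as<arma::vec>(f["coefficients"]);
      V = as<arma::mat>(f["vcov"]);
      if (d == 0 && ka == k) { warm = beta; warm_ok = true; }
    } else {                    // binomial ML
      List f = irls_fit_cpp(D, y, 25, 1e-8);
      beta = as<arma::vec>(f["coefficients"]);
      V = as<arma::mat>(f["vcov"]);
    }

    arma::vec muhat = beta.subvec(0, ka - 1);
    arma::mat S = V.submat(0, 0, ka - 1, ka - 1);
    if (p > 0) {
      arma::vec bcov = beta.subvec(ka, ka + p - 1);
      muhat += arma::as_scalar(xbar * bcov);
      arma::mat Vdb = V.submat(0, ka, ka - 1, ka + p - 1);
      arma::mat Vbb = V.submat(ka, ka, ka + p - 1, ka + p - 1);
      arma::vec a = Vdb * xbar.t();
      double q = arma::as_scalar(xbar * Vbb * xbar.t());
      S += a * arma::rowvec(ka, arma::fill::ones);
      S += arma::vec(ka, arma::fill::ones) * a.t();
      S += q;
    }

    bool use_fixed = !recompute && ka == k;
    double best = -arma::datum::inf;
    bool any = false;
    for (int m = 0; m < M; ++m) {
      arma::vec mu0a(ka);
      for (int a = 0; a < ka; ++a) mu0a(a) = mu0(active(a), m);
      arma::vec c;
      if (use_fixed) {
        c = Cfix.col(m);
        if (arma::norm(c, 2) < 1e-14) continue;
      } else if (!contrast_from_cov(mu0a, S, c)) continue;
      double den = arma::as_scalar(c.t() * S * c);
      if (den <= 0) continue;
      double t = arma::dot(c, muhat) / std::sqrt(den);
      if (t > best) best = t;
      any = true;
    }
    out(d) = any ? best : 0.0;
  }
  return out;
}

// Residual-based statistic S2 for a batch of assignment sequences.
// r: residuals from the covariate-only fit (held fixed across draws);
// contrasts come from realized per-arm sample sizes as the weight vector
// (Cfix is used when every draw realizes the same full-arm counts).
// [[Rcpp::export]]
arma::vec s2_stat_batch_cpp(const arma::imat& Z, const arma::vec& r,
                            const arma::mat& mu0, bool recompute,
                            const arma::mat& Cfix) {
  const int ndraw = Z.n_rows, n = Z.n_cols;
  const int k = mu0.n_rows, M = mu0.n_cols;
  arma::vec out(ndraw);
  for (int d = 0; d < ndraw; ++d) {
    arma::vec sum(k, arma::fill::zeros), ssq(k, arma::fill::zeros);
    arma::ivec cnt(k, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      int j = Z(d, i) - 1;
      cnt(j)++; sum(j) += r(i); ssq(j) += r(i) * r(i);
    }
    arma::uvec active = arma::find(cnt > 0);
    const int ka = active.n_elem;
    if (ka < 2) { out(d) = 0.0; continue; }
    arma::vec mbar(ka), s2(ka), nn(ka);
    for (int a = 0; a < ka; ++a) {
      int j = active(a);
      nn(a) = cnt(j);
      mbar(a) = sum(j) / cnt(j);
      s2(a) = (cnt(j) > 1)
        ? (ssq(j) - cnt(j) * mbar(a) * mbar(a)) / (cnt(j) - 1.0)
        : 0.0;
      if (s2(a) < 0) s2(a) = 0;
    }
    bool use_fixed = !recompute && ka == k;
    double best = -arma::datum::inf;
    bool any = false;
    for (int m = 0; m < M; ++m) {
      arma::vec c;
      if (use_fixed) {
        c = Cfix.col(m);
      } else {
        arma::vec mu0a(ka);
        for (int a = 0; a < ka; ++a) mu0a(a) = mu0(active(a), m);
        arma::mat S = arma::diagmat(1.0 / nn);
        if (!contrast_from_cov(mu0a, S, c)) continue;
      }
      double num = arma::dot(c, mbar);
      double den2 = arma::dot(c % c, s2 / nn);
      double t;
      if (den2 <= 0) {
        // degenerate within-arm variances: sign of the numerator decides
        t = (num > 0) ? arma::datum::inf
                      : ((num < 0) ? -arma::datum::inf : 0.0);
      } else {
        t = num / std::sqrt(den2);
      }
      if (t > best) best = t;
      any = true;
    }
    out(d) = any ? best : 0.0;
  }
  return out;
}
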