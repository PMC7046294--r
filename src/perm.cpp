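// Checkerboard-swap MCMC over the fixed-margin class of a binary matrix,
// and a small Newton solver for the logistic Wald Z used inside the
// permutation test. R's RNG is used throughout so set.seed() controls
// everything.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// one attempted checkerboard swap restricted to the given column indices;
// returns 1 on success. cols are 0-based.
static int attempt_swap(IntegerMatrix &x, const std::vector<int> &cols) {
  int n = x.nrow(), m = (int)cols.size();
  if (n < 2 || m < 2) return 0;
  int r1 = (int)(unif_rand() * n);
  int r2 = (int)(unif_rand() * (n - 1));
  if (r2 >= r1) r2++;
  int ci = (int)(unif_rand() * m);
  int cj = (int)(unif_rand() * (m - 1));
  if (cj >= ci) cj++;
  int c1 = cols[ci], c2 = cols[cj];
  int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
  if (a == 1 && d == 1 && b == 0 && c == 0) {
    x(r1, c1) = 0; x(r2, c2) = 0; x(r1, c2) = 1; x(r2, c1) = 1;
    return 1;
  }
  if (a == 0 && d == 0 && b == 1 && c == 1) {
    x(r1, c1) = 1; x(r2, c2) = 1; x(r1, c2) = 0; x(r2, c1) = 0;
    return 1;
  }
  return 0;
}

// The chain uses lazy *trial* swaps: a uniformly proposed 2x2 submatrix is
// swapped only if it has the checkerboard pattern, and each attempt is
// additionally skipped with probability 1/2 (aperiodicity on tiny classes).
// Counting attempts (not successes) keeps the proposal symmetric and the
// stationary distribution exactly uniform over the margin class; a
// success-counting variant would bias the chain toward states with few
// swappable submatrices. Because the success rate can be very low on
// sparse matrices, the attempt budget per thinning step is calibrated
// during burn-in so each step performs about `target` swaps in
// expectation.
struct ChainCtl {
  double succ_rate;
  bool degenerate;
};

static int lazy_attempt(IntegerMatrix &x, const std::vector<int> &cols) {
  if (unif_rand() < 0.5) return 0;
  return attempt_swap(x, cols);
}

// burn-in: run until 10 * ones successes (or an attempt cap that declares
// the matrix swap-degenerate); estimates the per-attempt success rate
static void chain_init(IntegerMatrix &x, const std::vector<int> &cols,
                       int ones, ChainCtl *ctl) {
  ctl->succ_rate = 0.5;
  ctl->degenerate = false;
  if ((int)cols.size() < 2 || x.nrow() < 2 || ones == 0) {
    ctl->degenerate = true;
    return;
  }
  long target = 10L * std::max(ones, 1);
  long cap = 4000L * target;
  long succ = 0, att = 0;
  while (succ < target && att < cap) {
    succ += lazy_attempt(x, cols);
    att++;
  }
  if (succ == 0) {
    ctl->degenerate = true;
    return;
  }
  ctl->succ_rate = (double)succ / (double)att;
}

// one thinning step: fixed attempt budget aiming for `target` swaps
static void chain_thin(IntegerMatrix &x, const std::vector<int> &cols,
                       long target, ChainCtl *ctl) {
  if (ctl->degenerate) return;
  long att = (long)std::ceil((double)target / std::max(ctl->succ_rate, 1e-6));
  for (long i = 0; i < att; i++) lazy_attempt(x, cols);
}

static int count_ones(const IntegerMatrix &x, const std::vector<int> &cols) {
  int s = 0;
  for (size_t j = 0; j < cols.size(); j++)
    for (int i = 0; i < x.nrow(); i++) s += x(i, cols[j]);
  return s;
}

static void split_types(const IntegerVector &col_type,
                        std::vector<int> &amp, std::vector<int> &del) {
  for (int j = 0; j < col_type.size(); j++) {
    if (col_type[j] == 0) amp.push_back(j); else del.push_back(j);
  }
}

// [[Rcpp::export]]
List cpp_permute_fixed_margins(IntegerMatrix x0, IntegerVector col_type,
                               int n_emit, int burn_mult, int thin_mult) {
  std::vector<int> ca, cd;
  split_types(col_type, ca, cd);
  IntegerMatrix x = clone(x0);
  int ones_a = count_ones(x, ca), ones_d = count_ones(x, cd);
  ChainCtl ctla, ctld;
  chain_init(x, ca, ones_a, &ctla);
  chain_init(x, cd, ones_d, &ctld);
  (void)burn_mult;
  List out(n_emit);
  for (int e = 0; e < n_emit; e++) {
    chain_thin(x, ca, (long)thin_mult * std::max(ones_a, 1), &ctla);
    chain_thin(x, cd, (long)thin_mult * std::max(ones_d, 1), &ctld);
    out[e] = clone(x);
  }
  bool degenerate = (ctla.degenerate || ca.empty()) &&
    (ctld.degenerate || cd.empty());
  return List::create(_["matrices"] = out, _["degenerate"] = degenerate);
}

// Wald Z for the second column of the design matrix under a logistic model.
// Ridge-penalized restart on separation/non-convergence; returns NA only if
// even the penalized fit fails (e.g. constant predictor).
static double logistic_z(const arma::vec &y, const arma::mat &X, double lambda) {
  int p = (int)X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec penv(p, arma::fill::value(lambda));
  penv(0) = 0.0;
  arma::mat pen = arma::diagmat(penv);
  bool ok = false;
  for (int it = 0; it < 50; it++) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    arma::mat H = X.t() * (X.each_col() % w) + pen;
    arma::vec g = X.t() * (y - mu) - pen * beta;
    arma::vec step;
    if (!arma::solve(step, H, g, arma::solve_opts::no_approx)) {
      if (lambda == 0.0) return logistic_z(y, X, 1e-2);
      return NA_REAL;
    }
    beta += step;
    if (arma::abs(step).max() < 1e-10) { ok = true; break; }
    if (arma::abs(beta).max() > 30.0) break;
  }
  if (!ok && lambda == 0.0) return logistic_z(y, X, 1e-2);
  if (!beta.is_finite()) return NA_REAL;
  arma::vec eta = X * beta;
  arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
  arma::vec w = mu % (1.0 - mu);
  arma::mat H = X.t() * (X.each_col() % w) + pen;
  arma::mat Hinv;
  if (!arma::inv(Hinv, H)) {
    if (lambda == 0.0) return logistic_z(y, X, 1e-2);
    return NA_REAL;
  }
  double se = std::sqrt(Hinv(1, 1));
  if (!std::isfinite(se) || se <= 0) return NA_REAL;
  return beta(1) / se;
}

// [[Rcpp::export]]
double cpp_logistic_wald_z(NumericVector y, NumericMatrix X) {
  arma::vec ay(y.begin(), y.size(), false);
  arma::mat aX(X.begin(), X.nrow(), X.ncol(), false);
  return logistic_z(ay, aX, 0.0);
}

// Streamed permutation test: observed Z per column, then n_perm emissions of
// the margin-preserving chain, each scored with the same logistic model;
// returns exceedance counts for the two-sided empirical p.
// [[Rcpp::export]]
List cpp_scna_perm_test(IntegerMatrix x0, NumericVector y, NumericVector ps,
                        IntegerVector col_type, int n_perm,
                        int burn_mult, int thin_mult) {
  int n = x0.nrow(), m = x0.ncol();
  arma::vec ay(y.begin(), n, false);
  arma::mat X(n, 3);
  for (int i = 0; i < n; i++) { X(i, 0) = 1.0; X(i, 2) = ps[i]; }
  arma::vec z_obs(m);
  for (int j = 0; j < m; j++) {
    for (int i = 0; i < n; i++) X(i, 1) = x0(i, j);
    z_obs(j) = logistic_z(ay, X, 0.0);
  }
  std::vector<int> ca, cd;
  split_types(col_type, ca, cd);
  IntegerMatrix x = clone(x0);
  int ones_a = count_ones(x, ca), ones_d = count_ones(x, cd);
  ChainCtl ctla, ctld;
  chain_init(x, ca, ones_a, &ctla);
  chain_init(x, cd, ones_d, &ctld);
  (void)burn_mult;
  arma::ivec exceed(m, arma::fill::zeros);
  arma::ivec nulls_used(m, arma::fill::zeros);
  for (int e = 0; e < n_perm; e++) {
    chain_thin(x, ca, (long)thin_mult * std::max(ones_a, 1), &ctla);
    chain_thin(x, cd, (long)thin_mult * std::max(ones_d, 1), &ctld);
    for (int j = 0; j < m; j++) {
      for (int i = 0; i < n; i++) X(i, 1) = x(i, j);
      double z = logistic_z(ay, X, 0.0);
      if (ISNAN(z)) continue;
      nulls_used(j) += 1;
      if (std::fabs(z) >= std::fabs(z_obs(j))) exceed(j) += 1;
    }
    if (e % 256 == 0) Rcpp::checkUserInterrupt();
  }
  bool degenerate = (ctla.degenerate || ca.empty()) &&
    (ctld.degenerate || cd.empty());
  return List::create(_["z_obs"] = NumericVector(z_obs.begin(), z_obs.end()),
                      _["exceed"] = IntegerVector(exceed.begin(), exceed.end()),
                      _["nulls_used"] = IntegerVector(nulls_used.begin(), nulls_used.end()),
                      _["degenerate"] = degenerate);
}
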