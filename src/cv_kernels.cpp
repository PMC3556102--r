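// Hot loops for the resampling study: QDA retrained once per fold, with
// repetition and bootstrap-rejection loops kept in C++. All randomness goes
// through R's RNG (Rcpp::sample) so results are reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ClassTotals {
  arma::vec sum1, sum2;   // per-class feature sums
  arma::mat ssq1, ssq2;   // per-class sums of outer products x x'
  int m1, m2;
};

ClassTotals class_totals(const arma::mat& X, const arma::ivec& y) {
  const arma::uword p = X.n_cols;
  ClassTotals t;
  t.sum1.zeros(p); t.sum2.zeros(p);
  t.ssq1.zeros(p, p); t.ssq2.zeros(p, p);
  t.m1 = 0; t.m2 = 0;
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    arma::rowvec x = X.row(i);
    if (y[i] == 1) { t.sum1 += x.t(); t.ssq1 += x.t() * x; ++t.m1; }
    else           { t.sum2 += x.t(); t.ssq2 += x.t() * x; ++t.m2; }
  }
  return t;
}

// Scalar (p = 1) fast path: QDA reduces to two Gaussian log-densities.
int fold_miscount_1d(const arma::mat& X, const arma::ivec& y,
                     const ClassTotals& tot, const std::vector<int>& fold_rows,
                     bool unbiased, double logprior1, double logprior2) {
  double s1 = tot.sum1[0], s2 = tot.sum2[0];
  double q1 = tot.ssq1(0, 0), q2 = tot.ssq2(0, 0);
  int m1 = tot.m1, m2 = tot.m2;
  for (int r : fold_rows) {
    double x = X(r, 0);
    if (y[r] == 1) { s1 -= x; q1 -= x * x; --m1; }
    else           { s2 -= x; q2 -= x * x; --m2; }
  }
  if (m1 < 2 || m2 < 2) return -1;
  double mu1 = s1 / m1, mu2 = s2 / m2;
  double v1 = (q1 - m1 * mu1 * mu1) / (unbiased ? m1 - 1.0 : double(m1));
  double v2 = (q2 - m2 * mu2 * mu2) / (unbiased ? m2 - 1.0 : double(m2));
  if (!(v1 > 0.0) || !(v2 > 0.0)) return -1;
  double ld1 = std::log(v1), ld2 = std::log(v2);
  int miss = 0;
  for (int r : fold_rows) {
    double x = X(r, 0);
    double d1 = x - mu1, d2 = x - mu2;
    double sc1 = -0.5 * ld1 - 0.5 * d1 * d1 / v1 + logprior1;
    double sc2 = -0.5 * ld2 - 0.5 * d2 * d2 / v2 + logprior2;
    int pred = (sc1 >= sc2) ? 1 : 2;
    if (pred != y[r]) ++miss;
  }
  return miss;
}

// Reusable workspace so the per-fold loop does not allocate.
struct FoldWork {
  arma::vec s1, s2, mu1, mu2, z, x, d;
  arma::mat q1, q2, S1, S2, U1, U2;
  explicit FoldWork(arma::uword p)
    : s1(p), s2(p), mu1(p), mu2(p), z(p), x(p), d(p),
      q1(p, p), q2(p, p), S1(p, p), S2(p, p), U1(p, p), U2(p, p) {}
};

// Train QDA on the complement of one fold and count test misclassifications.
// Training moments are obtained by subtracting the fold's contribution from
// the full-sample totals. Returns -1 when a class covariance is not positive
// definite (degenerate training); ties in the discriminant go to class 1.
int fold_miscount(const arma::mat& X, const arma::ivec& y,
                  const ClassTotals& tot, const std::vector<int>& fold_rows,
                  bool unbiased, double logprior1, double logprior2,
                  FoldWork& w) {
  if (X.n_cols == 1)
    return fold_miscount_1d(X, y, tot, fold_rows, unbiased,
                            logprior1, logprior2);
  arma::vec& s1 = w.s1; arma::vec& s2 = w.s2;
  arma::mat& q1 = w.q1; arma::mat& q2 = w.q2;
  s1 = tot.sum1; s2 = tot.sum2; q1 = tot.ssq1; q2 = tot.ssq2;
  int m1 = tot.m1, m2 = tot.m2;
  for (int r : fold_rows) {
    w.x = X.row(r).t();
    if (y[r] == 1) { s1 -= w.x; q1 -= w.x * w.x.t(); --m1; }
    else           { s2 -= w.x; q2 -= w.x * w.x.t(); --m2; }
  }
  if (m1 < 2 || m2 < 2) return -1;
  w.mu1 = s1 / m1; w.mu2 = s2 / m2;
  double d1 = unbiased ? (m1 - 1.0) : double(m1);
  double d2 = unbiased ? (m2 - 1.0) : double(m2);
  w.S1 = (q1 - double(m1) * (w.mu1 * w.mu1.t())) / d1;
  w.S2 = (q2 - double(m2) * (w.mu2 * w.mu2.t())) / d2;
  if (!arma::chol(w.U1, arma::symmatu(w.S1))) return -1;
  if (!arma::chol(w.U2, arma::symmatu(w.S2))) return -1;
  double ld1 = 2.0 * arma::accu(arma::log(w.U1.diag()));
  double ld2 = 2.0 * arma::accu(arma::log(w.U2.diag()));
  if (!std::isfinite(ld1) || !std::isfinite(ld2)) return -1;
  int miss = 0;
  for (int r : fold_rows) {
    w.x = X.row(r).t();
    w.d = w.x - w.mu1;
    w.z = arma::solve(arma::trimatl(w.U1.t()), w.d);
    double sc1 = -0.5 * ld1 - 0.5 * arma::dot(w.z, w.z) + logprior1;
    w.d = w.x - w.mu2;
    w.z = arma::solve(arma::trimatl(w.U2.t()), w.d);
    double sc2 = -0.5 * ld2 - 0.5 * arma::dot(w.z, w.z) + logprior2;
    int pred = (sc1 >= sc2) ? 1 : 2;
    if (pred != y[r]) ++miss;
  }
  return miss;
}

// Misclassified count over a whole k-fold partition (fold ids 0..k-1).
int partition_miscount(const arma::mat& X, const arma::ivec& y, int k,
                       const std::vector<std::vector<int> >& folds,
                       bool unbiased, double lp1, double lp2) {
  ClassTotals tot = class_totals(X, y);
  FoldWork w(X.n_cols);
  int total = 0;
  for (int j = 0; j < k; ++j) {
    if (folds[j].empty()) continue;
    int m = fold_miscount(X, y, tot, folds[j], unbiased, lp1, lp2, w);
    if (m < 0) return -1;
    total += m;
  }
  return total;
}

// Random partition of n items into k folds with sizes differing by <= 1,
// via R's RNG. Returns fold membership lists; `assign` (length n) records
// the fold id of each row for optional replay.
std::vector<std::vector<int> > random_partition(int n, int k,
                                                IntegerVector& assign) {
  IntegerVector perm = Rcpp::sample(n, n, false); // 1-based permutation
  std::vector<std::vector<int> > folds(k);
  int base = n / k, extra = n % k, pos = 0;
  for (int j = 0; j < k; ++j) {
    int sz = base + (j < extra ? 1 : 0);
    for (int t = 0; t < sz; ++t, ++pos) {
      int row = perm[pos] - 1;
      folds[j].push_back(row);
      assign[row] = j + 1;
    }
  }
  return folds;
}

} // namespace

// [[Rcpp::export]]
int cpp_partition_miscount(const arma::mat& X, const arma::ivec& y,
                           const arma::ivec& fold, int k, bool unbiased,
                           double logprior1, double logprior2) {
  std::vector<std::vector<int> > folds(k);
  for (arma::uword i = 0; i < fold.n_elem; ++i)
    folds[fold[i] - 1].push_back(int(i));
  return partition_miscount(X, y, k, folds, unbiased, logprior1, logprior2);
}

// [[Rcpp::export]]
List cpp_repeated_kfold(const arma::mat& X, const arma::ivec& y, int k, int R,
                        bool unbiased, double logprior1, double logprior2,
                        bool record) {
  const int n = X.n_rows;
  NumericVector est(R);
  IntegerMatrix rec = record ? IntegerMatrix(R, n) : IntegerMatrix(0, 0);
  IntegerVector assign(n);
  for (int r = 0; r < R; ++r) {
    std::vector<std::vector<int> > folds = random_partition(n, k, assign);
    int m = partition_miscount(X, y, k, folds, unbiased, logprior1, logprior2);
    est[r] = (m < 0) ? NA_REAL : double(m) / n;
    if (record) for (int i = 0; i < n; ++i) rec(r, i) = assign[i];
  }
  return List::create(_["estimates"] = est,
                      _["folds"] = record ? SEXP(rec) : R_NilValue);
}

// Bootstrap cross-validation: per repetition draw a with-replacement sample
// of size n (optionally stratified within class), reject it until both
// classes contain at least `min_distinct` distinct source rows, then run
// k-fold CV (k == n gives LOOCV with each bootstrap member, duplicates
// included, left out once). Degenerate QDA training triggers a redraw of
// that bootstrap sample.
// [[Rcpp::export]]
List cpp_bootstrap_cv(const arma::mat& X, const arma::ivec& y, int k, int R,
                      bool stratified, int min_distinct, int max_redraws,
                      bool unbiased, double logprior1, double logprior2,
                      bool record) {
  const int n = X.n_rows;
  std::vector<int> idx1, idx2;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? idx1 : idx2).push_back(i);
  const int m1 = idx1.size(), m2 = idx2.size();

  NumericVector est(R);
  IntegerMatrix rec = record ? IntegerMatrix(R, n) : IntegerMatrix(0, 0);
  IntegerVector assign(n);
  std::vector<int> seen(n, -1);
  arma::uvec rows(n);
  arma::ivec yb(n);
  int total_redraws = 0, exhausted_at = 0;

  for (int r = 0; r < R; ++r) {
    int tries = 0;
    bool done = false;
    while (!done) {
      if (tries > max_redraws) { exhausted_at = r + 1; break; }
      // draw indices
      if (stratified) {
        IntegerVector d1 = Rcpp::sample(m1, m1, true);
        IntegerVector d2 = Rcpp::sample(m2, m2, true);
        for (int i = 0; i < m1; ++i) rows[i] = idx1[d1[i] - 1];
        for (int i = 0; i < m2; ++i) rows[m1 + i] = idx2[d2[i] - 1];
      } else {
        IntegerVector d = Rcpp::sample(n, n, true);
        for (int i = 0; i < n; ++i) rows[i] = d[i] - 1;
      }
      // distinct source rows per class (stamp array, one pass)
      int stamp = r * (max_redraws + 2) + tries;
      int dist1 = 0, dist2 = 0;
      for (int i = 0; i < n; ++i) {
        int s = rows[i];
        if (seen[s] != stamp) {
          seen[s] = stamp;
          if (y[s] == 1) ++dist1; else ++dist2;
        }
        yb[i] = y[s];
      }
      if (dist1 < min_distinct || dist2 < min_distinct) {
        ++tries; ++total_redraws; continue;
      }
      arma::mat Xb = X.rows(rows);
      std::vector<std::vector<int> > folds;
      if (k == n) {
        folds.assign(n, std::vector<int>());
        for (int i = 0; i < n; ++i) { folds[i].push_back(i); assign[i] = i + 1; }
      } else {
        folds = random_partition(n, k, assign);
      }
      int m = partition_miscount(Xb, yb, k, folds, unbiased,
                                 logprior1, logprior2);
      if (m < 0) { ++tries; ++total_redraws; continue; }
      est[r] = double(m) / n;
      if (record) for (int i = 0; i < n; ++i) rec(r, i) = int(rows[i]) + 1;
      done = true;
    }
    if (exhausted_at > 0) break;
  }
  return List::create(_["estimates"] = est,
                      _["redraws"] = total_redraws,
                      _["exhausted_at"] = exhausted_at,
                      _["indices"] = record ? SEXP(rec) : R_NilValue);
}
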