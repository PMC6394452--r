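// Linear soft-margin SVM / SVR solvers (dual coordinate descent).
//
// C-SVC dual:  min_a 1/2 a' Q a - e' a,  0 <= a_i <= C,  Q_ij = y_i y_j x_i'x_j
// eps-SVR dual: min_b 1/2 b' K b + eps * sum |b_i| - y' b,  -C <= b_i <= C
// The bias term is handled by the caller through an augmented constant
// feature, so w here already contains the (regularised) intercept.

#include <Rcpp.h>
using namespace Rcpp;

// dot product of row i of X (n x d, column-major) with w
static inline double row_dot(const NumericMatrix &X, int i, const std::vector<double> &w) {
  const int n = X.nrow(), d = X.ncol();
  double s = 0.0;
  for (int j = 0; j < d; ++j) s += X[(size_t)j * n + i] * w[j];
  return s;
}

static inline void row_axpy(const NumericMatrix &X, int i, double a, std::vector<double> &w) {
  const int n = X.nrow(), d = X.ncol();
  for (int j = 0; j < d; ++j) w[j] += a * X[(size_t)j * n + i];
}

// Fisher-Yates shuffle driven by R's RNG so results follow set.seed()
static void shuffle_idx(std::vector<int> &idx) {
  const int n = (int)idx.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export(name = ".dcd_svc")]]
List dcd_svc(NumericMatrix X, NumericVector y, double C,
             double tol = 1e-3, int max_iter = 1000) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double v = X[(size_t)j * n + i]; s += v * v; }
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  GetRNGstate();
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    shuffle_idx(idx);
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      if (qii[i] <= 0.0) continue;
      const double G = y[i] * row_dot(X, i, w) - 1.0;
      double PG = G;                       // projected gradient
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (PG != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0; else if (a_new > C) a_new = C;
        alpha[i] = a_new;
        if (a_new != a_old) row_axpy(X, i, (a_new - a_old) * y[i], w);
      }
    }
    if (max_pg < tol) { ++iter; break; }
  }
  PutRNGstate();

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iter"] = iter);
}

// [[Rcpp::export(name = ".dcd_svr")]]
List dcd_svr(NumericMatrix X, NumericVector y, double C, double eps_tube = 0.1,
             double tol = 1e-3, int max_iter = 1000) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), beta(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) { double v = X[(size_t)j * n + i]; s += v * v; }
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  GetRNGstate();
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    shuffle_idx(idx);
    double max_step = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      if (qii[i] <= 0.0) continue;
      const double G = row_dot(X, i, w) - y[i];   // gradient of smooth part
      // exact coordinate minimiser: soft-threshold then clip to [-C, C]
      const double z = beta[i] - G / qii[i];
      const double thr = eps_tube / qii[i];
      double b_new = (z > thr) ? z - thr : ((z < -thr) ? z + thr : 0.0);
      if (b_new > C) b_new = C; else if (b_new < -C) b_new = -C;
      const double db = b_new - beta[i];
      if (db != 0.0) {
        beta[i] = b_new;
        row_axpy(X, i, db, w);
        const double st = std::fabs(db) * std::sqrt(qii[i]);
        if (st > max_step) max_step = st;
      }
    }
    if (max_step < tol) { ++iter; break; }
  }
  PutRNGstate();

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["iter"] = iter);
}
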