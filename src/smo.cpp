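#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kernel matrix between rows of A (n x d) and rows of B (m x d).
// kernel: 0 = linear, 1 = RBF with parameter gamma.
// [[Rcpp::export(name = ".kernel_matrix")]]
NumericMatrix kernel_matrix(NumericMatrix A, NumericMatrix B,
                            int kernel, double gamma) {
  int n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      if (kernel == 0) {
        for (int k = 0; k < d; ++k) acc += A(i, k) * B(j, k);
        K(i, j) = acc;
      } else {
        for (int k = 0; k < d; ++k) {
          double diff = A(i, k) - B(j, k);
          acc += diff * diff;
        }
        K(i, j) = std::exp(-gamma * acc);
      }
    }
  }
  return K;
}

namespace {

struct SmoState {
  const NumericMatrix &K;
  const NumericVector &y;
  std::vector<double> alpha;
  std::vector<double> E;  // E_i = f(i) - y_i with f = sum_j a_j y_j K_ij + b
  double b;
  double C, tol, eps;
  int n, steps, max_steps;

  SmoState(const NumericMatrix &K_, const NumericVector &y_,
           double C_, double tol_, int max_steps_)
      : K(K_), y(y_), alpha(K_.nrow(), 0.0), E(K_.nrow()), b(0.0),
        C(C_), tol(tol_), eps(1e-12), n(K_.nrow()), steps(0),
        max_steps(max_steps_) {
    for (int i = 0; i < n; ++i) E[i] = -y[i];  // all alpha start at 0
  }

  bool take_step(int i1, int i2) {
    if (i1 == i2) return false;
    double a1 = alpha[i1], a2 = alpha[i2];
    double y1 = y[i1], y2 = y[i2], s = y1 * y2;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, a2 - a1);
      H = std::min(C, C + a2 - a1);
    } else {
      L = std::max(0.0, a1 + a2 - C);
      H = std::min(C, a1 + a2);
    }
    if (L >= H) return false;
    double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > eps) {
      a2new = a2 + y2 * (E[i1] - E[i2]) / eta;
      if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    } else {
      // degenerate curvature: evaluate objective change at the clip ends
      double c1 = y2 * (E[i1] - E[i2]);
      double objL = c1 * L - 0.5 * eta * (L - a2) * (L - a2);
      double objH = c1 * H - 0.5 * eta * (H - a2) * (H - a2);
      if (objL > objH + eps) a2new = L;
      else if (objH > objL + eps) a2new = H;
      else return false;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return false;
    double a1new = a1 + s * (a2 - a2new);
    double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    double b1 = b - E[i1] - d1 * k11 - d2 * k12;
    double b2 = b - E[i2] - d1 * k12 - d2 * k22;
    double bnew;
    if (a1new > eps && a1new < C - eps) bnew = b1;
    else if (a2new > eps && a2new < C - eps) bnew = b2;
    else bnew = 0.5 * (b1 + b2);
    double db = bnew - b;
    for (int k = 0; k < n; ++k)
      E[k] += d1 * K(i1, k) + d2 * K(i2, k) + db;
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    ++steps;
    return true;
  }

  bool examine(int i2) {
    double r2 = E[i2] * y[i2];
    if (!((r2 < -tol && alpha[i2] < C) || (r2 > tol && alpha[i2] > 0)))
      return false;
    // second-choice heuristic: maximize |E1 - E2| over non-bound points
    int best = -1;
    double gap = -1.0;
    for (int k = 0; k < n; ++k) {
      if (alpha[k] > eps && alpha[k] < C - eps) {
        double g = std::fabs(E[k] - E[i2]);
        if (g > gap) { gap = g; best = k; }
      }
    }
    if (best >= 0 && take_step(best, i2)) return true;
    for (int k = 0; k < n; ++k) {
      if (alpha[k] > eps && alpha[k] < C - eps && take_step(k, i2))
        return true;
    }
    for (int k = 0; k < n; ++k)
      if (take_step(k, i2)) return true;
    return false;
  }
};

}  // namespace

// Train a soft-margin C-SVM by sequential minimal optimization on a
// precomputed kernel matrix. y must be in {-1, +1}. Deterministic:
// no randomness is consumed. Returns alpha and intercept b with the
// decision function f(x) = sum_i alpha_i y_i K(x_i, x) + b.
// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix K, NumericVector y, double C,
               double tol, int max_steps) {
  int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("length(y) must match nrow(K)");
  SmoState st(K, y, C, tol, max_steps);
  int num_changed = 0;
  bool examine_all = true;
  int outer_guard = 0;
  while ((num_changed > 0 || examine_all) &&
         st.steps < max_steps && ++outer_guard < 10000) {
    num_changed = 0;
    if (examine_all) {
      for (int i = 0; i < n; ++i) num_changed += st.examine(i) ? 1 : 0;
    } else {
      for (int i = 0; i < n; ++i)
        if (st.alpha[i] > st.eps && st.alpha[i] < C - st.eps)
          num_changed += st.examine(i) ? 1 : 0;
    }
    if (examine_all) examine_all = false;
    else if (num_changed == 0) examine_all = true;
  }
  return List::create(_["alpha"] = NumericVector(st.alpha.begin(), st.alpha.end()),
                      _["b"] = st.b,
                      _["steps"] = st.steps);
}
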