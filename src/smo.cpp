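// Sequential minimal optimization for the C-SVC dual with a precomputed
// kernel matrix.  Second-order working-set selection and the pairwise
// update/clipping scheme follow the standard SMO formulation:
//   min 1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TAU = 1e-12;

// [[Rcpp::export]]
List smo_train(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 1000000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label size mismatch");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  while (iter < max_iter) {
    // working-set selection: i = argmax_{t in I_up} -y_t G_t
    int i = -1;
    double Gmax = -INFINITY, Gmax2 = -INFINITY;
    for (int t = 0; t < n; ++t) {
      if (y[t] == 1 && alpha[t] < C) {
        if (-G[t] >= Gmax) { Gmax = -G[t]; i = t; }
      } else if (y[t] == -1 && alpha[t] > 0) {
        if (G[t] >= Gmax) { Gmax = G[t]; i = t; }
      }
    }
    // j: second-order gain among I_low with violation
    int j = -1;
    double obj_min = INFINITY;
    if (i >= 0) {
      for (int t = 0; t < n; ++t) {
        if (y[t] == 1 && alpha[t] > 0) {
          double grad_diff = Gmax + G[t];
          if (G[t] >= Gmax2) Gmax2 = G[t];
          if (grad_diff > 0) {
            double quad = K(i, i) + K(t, t) - 2.0 * y[i] * K(i, t);
            if (quad <= 0) quad = TAU;
            double obj = -(grad_diff * grad_diff) / quad;
            if (obj <= obj_min) { obj_min = obj; j = t; }
          }
        } else if (y[t] == -1 && alpha[t] < C) {
          double grad_diff = Gmax - G[t];
          if (-G[t] >= Gmax2) Gmax2 = -G[t];
          if (grad_diff > 0) {
            double quad = K(i, i) + K(t, t) + 2.0 * y[i] * K(i, t);
            if (quad <= 0) quad = TAU;
            double obj = -(grad_diff * grad_diff) / quad;
            if (obj <= obj_min) { obj_min = obj; j = t; }
          }
        }
      }
    }
    if (i < 0 || j < 0 || Gmax + Gmax2 < eps) break;

    const double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t) {
      G[t] += (y[t] * y[i] * K(i, t)) * dai + (y[t] * y[j] * K(j, t)) * daj;
    }
    ++iter;
  }

  // rho: mean of y_i G_i over free support vectors, midpoint fallback
  double rho, sum_free = 0.0;
  int n_free = 0;
  double ub = INFINITY, lb = -INFINITY;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { sum_free += yG; ++n_free; }
    else if ((y[t] == 1 && alpha[t] >= C) || (y[t] == -1 && alpha[t] <= 0)) {
      if (yG > lb) lb = yG;
    } else {
      if (yG < ub) ub = yG;
    }
  }
  rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0);
  obj /= 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iter"] = iter, _["obj"] = obj,
                      _["converged"] = iter < max_iter);
}
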