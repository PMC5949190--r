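#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// SMO working-set solver for the soft-margin SVM dual on a precomputed
// Gram matrix:
//
//   min_a  (1/2) a' Q a - e' a,   Q_ij = y_i y_j K_ij
//   s.t.   y' a = 0,  0 <= a_i <= C
//
// Pair selection is the maximal-violating-pair rule with a second-order
// (quadratic gain) choice of the second index. One iteration = one pair
// update. Stops when the KKT violation max_{I_up}(-y_i g_i) -
// min_{I_low}(-y_i g_i) drops below tol. K is symmetric, so rows are
// read as columns for contiguous access.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C, double tol,
               int max_iter) {
  const int l = K.nrow();
  const double TAU = 1e-12;
  const double *Kp = REAL(K);
  const double *yp = REAL(y);
  std::vector<double> alpha(l, 0.0);
  std::vector<double> G(l, -1.0); // gradient of the dual objective
  std::vector<double> Kdiag(l);
  for (int t = 0; t < l; ++t) Kdiag[t] = Kp[(size_t)t * l + t];
  int iter = 0;
  bool converged = false;
  double gap = std::numeric_limits<double>::infinity();

  while (iter < max_iter) {
    // first index: largest -y_i G_i over I_up (can increase y_i a_i)
    int i = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < l; ++t) {
      bool up = (yp[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      if (up) {
        double v = -yp[t] * G[t];
        if (v > Gmax) { Gmax = v; i = t; }
      }
    }
    // second index: most negative second-order gain over I_low
    int j = -1;
    double Gmin = std::numeric_limits<double>::infinity();
    double obj_min = std::numeric_limits<double>::infinity();
    const double *Ki = (i >= 0) ? Kp + (size_t)i * l : NULL;
    const double Kii = (i >= 0) ? Kdiag[i] : 0.0;
    const double yi = (i >= 0) ? yp[i] : 0.0;
    for (int t = 0; t < l; ++t) {
      bool low = (yp[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (low) {
        double gt = -yp[t] * G[t];
        if (gt < Gmin) Gmin = gt;
        if (i >= 0) {
          double b = Gmax - gt;
          if (b > 0) {
            double a = Kii + Kdiag[t] - 2.0 * yi * yp[t] * Ki[t];
            if (a <= 0) a = TAU;
            double obj = -(b * b) / a;
            if (obj < obj_min) { obj_min = obj; j = t; }
          }
        }
      }
    }
    gap = Gmax - Gmin;
    if (i < 0 || j < 0 || gap < tol) { converged = true; break; }

    // analytic update of the pair, preserving y_i a_i + y_j a_j
    const double yj = yp[j];
    double a_ij = Kii + Kdiag[j] - 2.0 * yi * yj * Ki[j];
    if (a_ij <= 0) a_ij = TAU;
    double b_ij = -yi * G[i] + yj * G[j];
    double old_ai = alpha[i], old_aj = alpha[j];
    double sum = yi * old_ai + yj * old_aj;
    alpha[i] += yi * b_ij / a_ij;
    if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > C) alpha[i] = C;
    alpha[j] = yj * (sum - yi * alpha[i]);
    if (alpha[j] < 0) {
      alpha[j] = 0;
      alpha[i] = yi * sum;
      if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > C) alpha[i] = C;
    } else if (alpha[j] > C) {
      alpha[j] = C;
      alpha[i] = yi * (sum - yj * C);
      if (alpha[i] < 0) alpha[i] = 0; else if (alpha[i] > C) alpha[i] = C;
    }

    double dai = yi * (alpha[i] - old_ai), daj = yj * (alpha[j] - old_aj);
    if (dai != 0.0 || daj != 0.0) {
      const double *Kj = Kp + (size_t)j * l;
      for (int t = 0; t < l; ++t)
        G[t] += yp[t] * (Ki[t] * dai + Kj[t] * daj);
    }
    ++iter;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["kkt_gap"] = gap);
}
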