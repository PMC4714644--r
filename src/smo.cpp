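#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin linear SVM dual with
// per-sample box constraints 0 <= alpha_i <= C_i.  Per-sample upper bounds
// are what the semi-supervised trainer uses to weight unlabeled slacks
// (U_tmp) differently from labeled slacks (C).
//
// Dual: min  1/2 a'Qa - e'a,  Q_ij = y_i y_j K_ij
// s.t.  sum(a_i y_i) = 0,  0 <= a_i <= C_i.
//
// Working-set selection is the maximal-KKT-violating pair; problems here are
// tiny (tens of samples), so this converges to near machine precision.

// [[Rcpp::export]]
List smo_solve(const NumericMatrix& K, const NumericVector& y,
               const NumericVector& C, double tol = 1e-12,
               int max_iter = 2000000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  std::vector<double> grad(n, -1.0);  // grad_i = sum_j Q_ij a_j - 1

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // i maximizes -y_i grad_i over I_up, j minimizes it over I_low
    int i = -1, j = -1;
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * grad[t];
      bool up  = (y[t] > 0 && alpha[t] < C[t]) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C[t]);
      if (up && v > gmax)  { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    // analytic 2-variable step along direction (y_i e_i, -y_j e_j)
    double yi = y[i], yj = y[j];
    // curvature along the feasible direction (y_i e_i, -y_j e_j):
    // u'Qu = K_ii + K_jj - 2 K_ij (the y factors cancel inside Q)
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-300) quad = 1e-12;
    double step = (gmax - gmin) / quad;

    double ai = alpha[i], aj = alpha[j];
    double max_i = (yi > 0) ? (C[i] - ai) : ai;        // room for alpha_i
    double max_j = (yj > 0) ? aj : (C[j] - aj);        // room for alpha_j
    if (step > max_i) step = max_i;
    if (step > max_j) step = max_j;
    if (step <= 0) break;

    alpha[i] = ai + ((yi > 0) ? step : -step);
    alpha[j] = aj - ((yj > 0) ? step : -step);

    double dai = alpha[i] - ai, daj = alpha[j] - aj;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias from free support vectors; fall back to the midpoint of the KKT
  // feasibility interval when every alpha sits on a bound
  double bsum = 0.0; int bcnt = 0;
  double lo = -std::numeric_limits<double>::infinity();
  double hi =  std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    double wx = 0.0;
    for (int s = 0; s < n; ++s) wx += alpha[s] * y[s] * K(t, s);
    double margin = y[t] - wx;  // b that would put sample t exactly on margin
    bool at_lower = alpha[t] <= 1e-12;
    bool at_upper = alpha[t] >= C[t] - 1e-12;
    if (!at_lower && !at_upper) { bsum += margin; ++bcnt; }
    // y=+1 at alpha=0 needs w.x+b >= 1 (b >= margin); y=+1 at alpha=C has
    // active slack, w.x+b <= 1 (b <= margin); mirrored for y=-1
    if ((y[t] > 0 && at_lower) || (y[t] < 0 && at_upper))
      lo = std::max(lo, margin);
    if ((y[t] > 0 && at_upper) || (y[t] < 0 && at_lower))
      hi = std::min(hi, margin);
  }
  double b;
  if (bcnt > 0) b = bsum / bcnt;
  else if (std::isfinite(lo) && std::isfinite(hi)) b = 0.5 * (lo + hi);
  else if (std::isfinite(lo)) b = lo;
  else b = std::isfinite(hi) ? hi : 0.0;

  double dual = 0.0;
  for (int t = 0; t < n; ++t) dual -= alpha[t];
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 0)
      for (int s = 0; s < n; ++s)
        if (alpha[s] > 0)
          dual += 0.5 * alpha[t] * alpha[s] * y[t] * y[s] * K(t, s);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["dual_objective"] = dual,
                      _["iterations"] = iter);
}
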