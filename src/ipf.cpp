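#include <Rcpp.h>
using namespace Rcpp;

// Iterative proportional fitting of the conditional (quasi-independence
// given the total score) model. Margins over total scores are matched by
// construction; row and column margins are matched by alternating
// multiplicative updates of the score parameters. Convergence is the
// largest change of any fitted conditional split probability on the
// observed total scores between consecutive cycles.
// [[Rcpp::export]]
List cpp_ipf(NumericMatrix counts, NumericVector g1_init,
             NumericVector g2_init, double tol, int max_iter) {
  const int m1p = counts.nrow();
  const int m2p = counts.ncol();
  const int nd = m1p + m2p - 1;

  std::vector<double> row_obs(m1p, 0.0), col_obs(m2p, 0.0), nr(nd, 0.0);
  for (int i = 0; i < m1p; ++i)
    for (int j = 0; j < m2p; ++j) {
      double c = counts(i, j);
      row_obs[i] += c;
      col_obs[j] += c;
      nr[i + j] += c;
    }

  std::vector<double> g1(m1p), g2(m2p);
  for (int i = 0; i < m1p; ++i)
    g1[i] = row_obs[i] > 0 ? g1_init[i] : 0.0;
  for (int j = 0; j < m2p; ++j)
    g2[j] = col_obs[j] > 0 ? g2_init[j] : 0.0;

  std::vector<double> om(nd), t(nd), c1(m1p), c2(m2p);
  std::vector<double> p_old(m1p * m2p, R_PosInf), p_new(m1p * m2p, 0.0);

  auto compute_om = [&]() {
    std::fill(om.begin(), om.end(), 0.0);
    for (int i = 0; i < m1p; ++i) {
      if (g1[i] == 0.0) continue;
      for (int j = 0; j < m2p; ++j) om[i + j] += g1[i] * g2[j];
    }
    for (int r = 0; r < nd; ++r) t[r] = (nr[r] > 0 && om[r] > 0) ? nr[r] / om[r] : 0.0;
  };

  bool converged = false;
  double max_change = R_PosInf;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    compute_om();
    // convergence check on conditional split probabilities (observed r,
    // attainable cells)
    max_change = 0.0;
    for (int i = 0; i < m1p; ++i)
      for (int j = 0; j < m2p; ++j) {
        int idx = i + j * m1p;
        if (nr[i + j] > 0 && g1[i] > 0 && g2[j] > 0) {
          double p = g1[i] * g2[j] / om[i + j];
          double d = fabs(p - p_old[idx]);
          if (d > max_change) max_change = d;
          p_new[idx] = p;
        } else {
          p_new[idx] = 0.0;
        }
      }
    std::swap(p_old, p_new);
    if (max_change <= tol) { converged = true; break; }

    // row update
    for (int i = 0; i < m1p; ++i) {
      if (row_obs[i] <= 0) { g1[i] = 0.0; continue; }
      double s = 0.0;
      for (int j = 0; j < m2p; ++j) s += t[i + j] * g2[j];
      g1[i] = row_obs[i] / s;
    }
    compute_om();
    // column update
    for (int j = 0; j < m2p; ++j) {
      if (col_obs[j] <= 0) { g2[j] = 0.0; continue; }
      double s = 0.0;
      for (int i = 0; i < m1p; ++i) s += t[i + j] * g1[i];
      g2[j] = col_obs[j] / s;
    }
    double mx1 = 0.0, mx2 = 0.0;
    for (int i = 0; i < m1p; ++i) if (g1[i] > mx1) mx1 = g1[i];
    for (int j = 0; j < m2p; ++j) if (g2[j] > mx2) mx2 = g2[j];
    for (int i = 0; i < m1p; ++i) g1[i] /= mx1;
    for (int j = 0; j < m2p; ++j) g2[j] /= mx2;
  }

  return List::create(_["g1"] = NumericVector(g1.begin(), g1.end()),
                      _["g2"] = NumericVector(g2.begin(), g2.end()),
                      _["converged"] = converged,
                      _["iterations"] = iter,
                      _["max_change"] = max_change);
}
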