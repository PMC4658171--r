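#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fifth-order WENO reconstruction of an upwind (positive-wind) flux at the
// right interface of the central cell, from the five cell values f_{i-2..i+2}.
static inline double weno5_rec(double fm2, double fm1, double f0,
                               double fp1, double fp2) {
  const double eps = 1e-6;
  const double q0 = (2.0 * fm2 - 7.0 * fm1 + 11.0 * f0) / 6.0;
  const double q1 = (-fm1 + 5.0 * f0 + 2.0 * fp1) / 6.0;
  const double q2 = (2.0 * f0 + 5.0 * fp1 - fp2) / 6.0;
  double a, b;
  a = fm2 - 2.0 * fm1 + f0; b = fm2 - 4.0 * fm1 + 3.0 * f0;
  const double b0 = 13.0 / 12.0 * a * a + 0.25 * b * b;
  a = fm1 - 2.0 * f0 + fp1; b = fm1 - fp1;
  const double b1 = 13.0 / 12.0 * a * a + 0.25 * b * b;
  a = f0 - 2.0 * fp1 + fp2; b = 3.0 * f0 - 4.0 * fp1 + fp2;
  const double b2 = 13.0 / 12.0 * a * a + 0.25 * b * b;
  const double w0 = 0.1 / ((eps + b0) * (eps + b0));
  const double w1 = 0.6 / ((eps + b1) * (eps + b1));
  const double w2 = 0.3 / ((eps + b2) * (eps + b2));
  return (w0 * q0 + w1 * q1 + w2 * q2) / (w0 + w1 + w2);
}

// Conservative advection right-hand side -div(v P) on the interior nodes of
// a uniform grid with spacing h. Fifth-order WENO finite-difference fluxes
// with global Lax-Friedrichs splitting per direction; the field and the
// fluxes are taken to vanish beyond the boundary (the tumour is assumed to
// stay away from the domain edge).
// [[Rcpp::export]]
NumericMatrix weno5_adv_rhs(const NumericMatrix& P, const NumericMatrix& vx,
                            const NumericMatrix& vy, double h) {
  const int n = P.nrow(), m = P.ncol();
  NumericMatrix rhs(n, m);

  double ax = 0.0, ay = 0.0;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      ax = std::max(ax, std::fabs(vx(i, j)));
      ay = std::max(ay, std::fabs(vy(i, j)));
    }

  // x-direction sweeps (index i varies along a column)
  {
    std::vector<double> fp(n + 6, 0.0), fm(n + 6, 0.0), fhat(n + 1, 0.0);
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i) {
        const double f = vx(i, j) * P(i, j);
        fp[i + 3] = 0.5 * (f + ax * P(i, j));
        fm[i + 3] = 0.5 * (f - ax * P(i, j));
      }
      for (int k = 0; k <= 2; ++k) { fp[k] = fm[k] = fp[n + 3 + k] = fm[n + 3 + k] = 0.0; }
      for (int k = 0; k <= n; ++k) {   // interface k = right face of cell k (1-based)
        const int c = k + 2;           // padded index of cell k
        fhat[k] = weno5_rec(fp[c - 2], fp[c - 1], fp[c], fp[c + 1], fp[c + 2]) +
                  weno5_rec(fm[c + 3], fm[c + 2], fm[c + 1], fm[c], fm[c - 1]);
      }
      for (int i = 0; i < n; ++i)
        rhs(i, j) -= (fhat[i + 1] - fhat[i]) / h;
    }
  }

  // y-direction sweeps (index j varies along a row)
  {
    std::vector<double> fp(m + 6, 0.0), fm(m + 6, 0.0), fhat(m + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < m; ++j) {
        const double f = vy(i, j) * P(i, j);
        fp[j + 3] = 0.5 * (f + ay * P(i, j));
        fm[j + 3] = 0.5 * (f - ay * P(i, j));
      }
      for (int k = 0; k <= 2; ++k) { fp[k] = fm[k] = fp[m + 3 + k] = fm[m + 3 + k] = 0.0; }
      for (int k = 0; k <= m; ++k) {
        const int c = k + 2;
        fhat[k] = weno5_rec(fp[c - 2], fp[c - 1], fp[c], fp[c + 1], fp[c + 2]) +
                  weno5_rec(fm[c + 3], fm[c + 2], fm[c + 1], fm[c], fm[c - 1]);
      }
      for (int j = 0; j < m; ++j)
        rhs(i, j) -= (fhat[j + 1] - fhat[j]) / h;
    }
  }
  return rhs;
}
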