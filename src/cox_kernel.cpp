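#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Log partial likelihood and derivatives for a Cox model whose linear
// predictor has the strain-panel structure
//
//   eta_i = x_i * beta  (+ x_i * u[strain_i] if with_u)  (+ a[strain_i] if with_a)
//
// with Efron handling of tied death times. Parameter layout is
// theta = (beta, u_1..u_J[, a_1..a_J]); the caller passes eta directly so the
// same kernel serves plain, stratum-free and penalized fits.
//
// Records must be sorted by increasing age. x is the 0/1 diet indicator,
// strain is a 1-based strain index (ignored when !with_u && !with_a).
// want: 0 = loglik only, 1 = + gradient, 2 = + Hessian (of the loglik, so
// negative definite).
//
// [[Rcpp::export]]
List cox_efron_deriv(NumericVector age, IntegerVector event, IntegerVector x,
                     IntegerVector strain, int nstrain, NumericVector eta,
                     bool with_u, bool with_a, int want) {
  const int n = age.size();
  const int J = nstrain;
  const int p = 1 + (with_u ? J : 0) + (with_a ? J : 0);
  const int off_u = 1;
  const int off_a = 1 + (with_u ? J : 0);
  const bool strata = with_u || with_a;

  double loglik = 0.0;
  std::vector<double> grad(want >= 1 ? p : 0, 0.0);
  std::vector<double> H(want >= 2 ? (size_t)p * p : 0, 0.0);

  // risk-set sums of exp(eta), accumulated from oldest age down
  double S0 = 0.0, Sx = 0.0;
  std::vector<double> Sxj(strata ? J : 0, 0.0), Sj(strata ? J : 0, 0.0);
  std::vector<double> Dxj(strata ? J : 0), Dj(strata ? J : 0);
  std::vector<double> m(want >= 2 ? p : 0);

  int i = n - 1;
  while (i >= 0) {
    const double t = age[i];
    int g = i;
    double D0 = 0.0, Dx = 0.0;
    int d = 0;
    if (strata) { std::fill(Dxj.begin(), Dxj.end(), 0.0);
                  std::fill(Dj.begin(), Dj.end(), 0.0); }
    // add the tie group [g..i] to the risk set, collect its deaths
    while (g >= 0 && age[g] == t) {
      const double w = std::exp(eta[g]);
      const int sj = strata ? (strain[g] - 1) : 0;
      S0 += w;
      if (x[g]) Sx += w;
      if (strata) { Sj[sj] += w; if (x[g]) Sxj[sj] += w; }
      if (event[g]) {
        ++d;
        loglik += eta[g];
        D0 += w;
        if (x[g]) Dx += w;
        if (strata) { Dj[sj] += w; if (x[g]) Dxj[sj] += w; }
        if (want >= 1) {
          if (x[g]) {
            grad[0] += 1.0;
            if (with_u) grad[off_u + sj] += 1.0;
          }
          if (with_a) grad[off_a + sj] += 1.0;
        }
      }
      --g;
    }
    for (int k = 0; k < d; ++k) {
      const double r = (double)k / d;
      const double phi = S0 - r * D0;
      loglik -= std::log(phi);
      if (want >= 1) {
        const double mb = Sx - r * Dx;
        grad[0] -= mb / phi;
        if (with_u)
          for (int j = 0; j < J; ++j) grad[off_u + j] -= (Sxj[j] - r * Dxj[j]) / phi;
        if (with_a)
          for (int j = 0; j < J; ++j) grad[off_a + j] -= (Sj[j] - r * Dj[j]) / phi;
        if (want >= 2) {
          m[0] = mb;
          if (with_u)
            for (int j = 0; j < J; ++j) m[off_u + j] = Sxj[j] - r * Dxj[j];
          if (with_a)
            for (int j = 0; j < J; ++j) m[off_a + j] = Sj[j] - r * Dj[j];
          const double inv = 1.0 / phi, inv2 = inv * inv;
          // l'' accumulates  m m^T / phi^2  -  Q / phi  (upper triangle)
          for (int a = 0; a < p; ++a) {
            const double ma = m[a] * inv2;
            double *row = &H[(size_t)a * p];
            for (int b = a; b < p; ++b) row[b] += ma * m[b];
          }
          // Q is sparse: x and x*I(strain=j) products collapse back onto the
          // weighted sums already in m (x is 0/1), strain blocks are diagonal
          H[0] -= mb * inv; // (beta, beta)
          if (with_u)
            for (int j = 0; j < J; ++j) {
              const double mx = m[off_u + j] * inv;
              H[(size_t)0 * p + off_u + j] -= mx;              // (beta, u_j)
              H[(size_t)(off_u + j) * p + off_u + j] -= mx;    // (u_j, u_j)
            }
          if (with_a)
            for (int j = 0; j < J; ++j) {
              const double mx = (Sxj[j] - r * Dxj[j]) * inv;
              const double maj = m[off_a + j] * inv;
              H[(size_t)0 * p + off_a + j] -= mx;              // (beta, a_j)
              if (with_u)
                H[(size_t)(off_u + j) * p + off_a + j] -= mx;  // (u_j, a_j)
              H[(size_t)(off_a + j) * p + off_a + j] -= maj;   // (a_j, a_j)
            }
        }
      }
    }
    i = g;
  }

  List out = List::create(Named("loglik") = loglik);
  if (want >= 1) out["grad"] = NumericVector(grad.begin(), grad.end());
  if (want >= 2) {
    NumericMatrix Hm(p, p);
    for (int a = 0; a < p; ++a)
      for (int b = a; b < p; ++b) {
        Hm(a, b) = H[(size_t)a * p + b];
        Hm(b, a) = Hm(a, b);
      }
    out["hessian"] = Hm;
  }
  return out;
}
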