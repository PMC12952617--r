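#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-state periodic-HMM machinery. State 1 = inactive, state 2 = active.
// p12[t] is the probability of switching 1 -> 2 between bin t and bin t+1,
// driven by the time-of-day covariate of bin t (0-based here).
//
// Emission densities arrive pre-exponentiated and row-rescaled (each row of
// `dens` is exp(logdens - rowmax); the summed row maxima are added back by
// the R callers), so the forward loop is pure multiply-adds.

static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Periodically stationary distribution at cycle position 0: the left
// eigenvector of the product Gamma_0 Gamma_1 ... Gamma_{C-1}. For a 2x2
// stochastic matrix M the stationary vector is (M21, M12)/(M12 + M21).
static void stationary_cycle(const std::vector<double>& p12c,
                             const std::vector<double>& p21c,
                             double& d1, double& d2) {
  double m11 = 1.0, m12 = 0.0, m21 = 0.0, m22 = 1.0;
  const int C = (int)p12c.size();
  for (int k = 0; k < C; ++k) {
    const double g12 = p12c[k], g21 = p21c[k];
    const double a11 = 1.0 - g12, a12 = g12, a21 = g21, a22 = 1.0 - g21;
    const double n11 = m11 * a11 + m12 * a21;
    const double n12 = m11 * a12 + m12 * a22;
    const double n21 = m21 * a11 + m22 * a21;
    const double n22 = m21 * a12 + m22 * a22;
    m11 = n11; m12 = n12; m21 = n21; m22 = n22;
  }
  double denom = m12 + m21;
  if (denom < 1e-300) { d1 = 0.5; d2 = 0.5; return; }
  d1 = m21 / denom;
  d2 = m12 / denom;
}

// Scaled forward algorithm on rescaled densities; returns the log-likelihood
// up to the caller's additive rescaling constant.
static double fwd_ll(const NumericMatrix& dens,
                     const std::vector<double>& p12,
                     const std::vector<double>& p21,
                     double d1, double d2) {
  const int T = dens.nrow();
  const double* e1 = &dens(0, 0);
  const double* e2 = &dens(0, 1);
  double a1 = d1 * e1[0];
  double a2 = d2 * e2[0];
  if (a1 + a2 <= 0.0) return R_NegInf;
  double ll = 0.0;
  // lazy rescaling: the mass only shrinks (dens <= 1), so renormalize just
  // when it nears the underflow threshold
  for (int t = 1; t < T; ++t) {
    const double g12 = p12[t - 1], g21 = p21[t - 1];
    const double b1 = (a1 * (1.0 - g12) + a2 * g21) * e1[t];
    const double b2 = (a1 * g12 + a2 * (1.0 - g21)) * e2[t];
    a1 = b1; a2 = b2;
    const double s = a1 + a2;
    if (s <= 0.0) return R_NegInf;
    if (s < 1e-250) { ll += std::log(s); a1 /= s; a2 /= s; }
  }
  return ll + std::log(a1 + a2);
}

// [[Rcpp::export]]
NumericVector C_stationary(NumericVector p12c, NumericVector p21c) {
  std::vector<double> a(p12c.begin(), p12c.end());
  std::vector<double> b(p21c.begin(), p21c.end());
  double d1, d2;
  stationary_cycle(a, b, d1, d2);
  return NumericVector::create(d1, d2);
}

// Conditional log-likelihood of one series given random intercepts (u12, u21).
// eta12/eta21: linear predictors of the switching logits per bin (length T);
// eta12c/eta21c: one full 24-h cycle of predictors starting at the series'
// first-bin phase (used for the periodically stationary initial
// distribution). `logscale` is the additive constant removed from the
// densities.
// [[Rcpp::export]]
double C_cond_ll(NumericMatrix dens, double logscale,
                 NumericVector eta12, NumericVector eta21,
                 NumericVector eta12c, NumericVector eta21c,
                 double u12, double u21) {
  const int T = dens.nrow();
  const int C = eta12c.size();
  std::vector<double> p12(T), p21(T);
  for (int t = 0; t < T; ++t) {
    p12[t] = plogis_(eta12[t] + u12);
    p21[t] = plogis_(eta21[t] + u21);
  }
  std::vector<double> p12c(C), p21c(C);
  for (int k = 0; k < C; ++k) {
    p12c[k] = plogis_(eta12c[k] + u12);
    p21c[k] = plogis_(eta21c[k] + u21);
  }
  double d1, d2;
  stationary_cycle(p12c, p21c, d1, d2);
  double ll = fwd_ll(dens, p12, p21, d1, d2);
  return R_finite(ll) ? ll + logscale : ll;
}

// Negative marginal log-likelihood over flies, integrating the two
// independent random intercepts by Gauss-Hermite quadrature:
//   integral L(u) N(u; 0, sigma^2) du ~= sum_k (w_k / sqrt(pi)) L(sqrt(2) sigma x_k)
// applied per dimension (tensor product over the two switching intercepts).
// All flies share the time base, so eta vectors are common. dens_list /
// logscales follow the rescaling convention above.
// [[Rcpp::export]]
double C_marginal_nll(List dens_list, NumericVector logscales,
                      NumericVector eta12, NumericVector eta21,
                      NumericVector eta12c, NumericVector eta21c,
                      double sigma, NumericVector gh_x, NumericVector gh_w) {
  const int T = eta12.size();
  const int C = eta12c.size();
  const int Q = gh_x.size();
  const int nfly = dens_list.size();
  const int nnode = Q * Q;
  const double sq2s = std::sqrt(2.0) * sigma;

  std::vector< std::vector<double> > P12(nnode), P21(nnode);
  std::vector<double> D1(nnode), D2(nnode), logw(nnode);
  int idx = 0;
  for (int i = 0; i < Q; ++i) {
    for (int j = 0; j < Q; ++j, ++idx) {
      const double u12 = sq2s * gh_x[i];
      const double u21 = sq2s * gh_x[j];
      P12[idx].resize(T); P21[idx].resize(T);
      for (int t = 0; t < T; ++t) {
        P12[idx][t] = plogis_(eta12[t] + u12);
        P21[idx][t] = plogis_(eta21[t] + u21);
      }
      std::vector<double> p12c(C), p21c(C);
      for (int k = 0; k < C; ++k) {
        p12c[k] = plogis_(eta12c[k] + u12);
        p21c[k] = plogis_(eta21c[k] + u21);
      }
      stationary_cycle(p12c, p21c, D1[idx], D2[idx]);
      logw[idx] = std::log(gh_w[i]) + std::log(gh_w[j]) - std::log(M_PI);
    }
  }

  double nll = 0.0;
  std::vector<double> lls(nnode);
  for (int f = 0; f < nfly; ++f) {
    NumericMatrix dens = dens_list[f];
    double mx = R_NegInf;
    for (int k = 0; k < nnode; ++k) {
      lls[k] = logw[k] + fwd_ll(dens, P12[k], P21[k], D1[k], D2[k]);
      if (lls[k] > mx) mx = lls[k];
    }
    if (!R_finite(mx)) return 1e10;  // underflow guard for the optimizer
    double s = 0.0;
    for (int k = 0; k < nnode; ++k) s += std::exp(lls[k] - mx);
    nll -= mx + std::log(s) + logscales[f];
  }
  return nll;
}
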