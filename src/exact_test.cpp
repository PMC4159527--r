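#include <Rcpp.h>
#include <vector>
#include <cmath>

// Negative-binomial exact test on the conditional split distribution.
//
// Group sums A and B are modelled as NB(n_A*mu, size n_A/phi) and
// NB(n_B*mu, size n_B/phi) on library-size-equalized counts (sum of iid
// NB samples sharing a dispersion is NB with summed size). Conditional on
// the total N = A + B the success probability cancels, leaving a
// negative-hypergeometric weight
//   w(a) = C(a + rA - 1, a) * C(N - a + rB - 1, N - a),
// and for phi = 0 the Poisson limit, a Binomial(N, n_A/(n_A+n_B)) weight.
// The two-sided p-value is the minimum-likelihood rule: the total weight
// of all splits no more probable than the observed one.
//
// Weights are built by the multiplicative recurrence
//   w(a+1)/w(a) = (rA + a)(N - a) / ((a + 1)(rB + N - a - 1)),
// kept in double precision with a base-1e150 era counter so the hot loop
// needs no log/exp calls. Eras overlap (a raw value spans 300 decades),
// so cross-era comparisons rescale by 1e150 explicitly.

namespace {

const double ERA = 1e150;
const double ERA_INV = 1e-150;

// running sum over (mantissa, era) pairs; values more than two eras
// below the current reference are below double precision and dropped
struct ScaledSum {
  double s;
  int e;
  bool empty;
  ScaledSum() : s(0.0), e(0), empty(true) {}
  void add(double w, int we) {
    if (empty) { s = w; e = we; empty = false; return; }
    int de = we - e;
    if (de == 0) { s += w; }
    else if (de == -1) { s += w * ERA_INV; }
    else if (de == -2) { s += w * ERA_INV * ERA_INV; }
    else if (de > 0) {
      double f = (de == 1) ? ERA_INV : (de == 2 ? ERA_INV * ERA_INV : 0.0);
      s = s * f + w;
      e = we;
    }
    // de < -2: negligible
    if (s > ERA) { s *= ERA_INV; e += 1; }
  }
};

// is w_a * ERA^e_a <= w_o * ERA^e_o * (1 + tol)?
inline bool no_more_probable(double wa, int ea, double wo, int eo, double tol) {
  int de = ea - eo;
  if (de <= -2) return true;
  if (de >= 2) return false;
  double rhs = wo * (1.0 + tol);
  if (de == 1) return wa * ERA <= rhs;
  if (de == -1) return wa <= rhs * ERA;
  return wa <= rhs;
}

double exact_pval_one(double yA, double yB, double nA, double nB,
                      double phi, double tol,
                      std::vector<double> &w, std::vector<int> &er) {
  double N = yA + yB;
  if (N <= 0) return 1.0;
  R_xlen_t Ni = (R_xlen_t) std::llround(N);
  if ((R_xlen_t) w.size() < Ni + 1) { w.resize(Ni + 1); er.resize(Ni + 1); }

  const bool poisson = (phi <= 0.0);
  const double rA = poisson ? 0.0 : nA / phi;
  const double rB = poisson ? 0.0 : nB / phi;
  const double f = nA / nB;

  double v = 1.0;
  int e = 0;
  w[0] = v; er[0] = 0;
  for (R_xlen_t a = 0; a < Ni; ++a) {
    double da = (double) a;
    double ratio;
    if (poisson) {
      ratio = f * (N - da) / (da + 1.0);
    } else {
      ratio = (rA + da) * (N - da) / ((da + 1.0) * (rB + N - da - 1.0));
    }
    v *= ratio;
    if (v > ERA) { v *= ERA_INV; ++e; }
    else if (v < ERA_INV) { v *= ERA; --e; }
    w[a + 1] = v; er[a + 1] = e;
  }

  R_xlen_t aobs = (R_xlen_t) std::llround(yA);
  double wo = w[aobs];
  int eo = er[aobs];

  ScaledSum tot, sel;
  for (R_xlen_t a = 0; a <= Ni; ++a) {
    tot.add(w[a], er[a]);
    if (no_more_probable(w[a], er[a], wo, eo, tol)) sel.add(w[a], er[a]);
  }

  double p = sel.s / tot.s;
  int de = sel.e - tot.e;
  while (de < 0) { p *= ERA_INV; ++de; }
  if (p > 1.0) p = 1.0;
  if (p <= 0.0) p = 5e-324;  // observed split always qualifies
  return p;
}

}  // namespace

// [[Rcpp::export(name = ".nb_exact_pvals_cpp")]]
Rcpp::NumericVector nb_exact_pvals_cpp(Rcpp::NumericVector yA,
                                       Rcpp::NumericVector yB,
                                       double nA, double nB,
                                       double phi, double tol) {
  R_xlen_t m = yA.size();
  Rcpp::NumericVector out(m);
  std::vector<double> w;
  std::vector<int> er;
  for (R_xlen_t i = 0; i < m; ++i) {
    out[i] = exact_pval_one(yA[i], yB[i], nA, nB, phi, tol, w, er);
  }
  return out;
}
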