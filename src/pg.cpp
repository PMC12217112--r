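#include <Rcpp.h>
using namespace Rcpp;

// Exact Polya-Gamma sampling via the alternating-series accept-reject
// scheme of Devroye (2009) as used for Bayesian logistic models by
// Polson, Scott & Windle (2013).  PG(1, c) = J*(1, |c|/2) / 4 and
// PG(b, c) for integer b is the sum of b independent PG(1, c) draws
// (exposures here are small comparison counts, so the sum is cheap).
//
// All randomness goes through R's RNG so set.seed() governs draws.

static const double TRUNC = 0.64;            // series crossover point t
static const double PI2_8 = M_PI * M_PI / 8.0;

// Inverse-Gaussian(mu = 1/z, lambda = 1) cdf at t, z >= 0, on log-safe form.
static double pigauss(double t, double z) {
  double s = std::sqrt(t);
  double a = R::pnorm((t * z - 1.0) / s, 0.0, 1.0, 1, 0);
  // exp(2z) * Phi(-(tz+1)/sqrt(t)) computed in logs to dodge overflow
  double logb = 2.0 * z + R::pnorm(-(t * z + 1.0) / s, 0.0, 1.0, 1, 1);
  return a + std::exp(logb);
}

// nth series coefficient a_n(x) of the J*(1, .) density
static double acoef(int n, double x) {
  double np = n + 0.5;
  if (x <= TRUNC) {
    return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np * np / x);
  }
  return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
}

// Inverse-Gaussian(1/z, 1) truncated to (0, t]; z may be 0 (Levy limit).
static double rtigauss(double z, double t) {
  double x = t + 1.0;
  if (1.0 / t < z) {          // mu <= t: draw IG until it lands below t
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  } else {                    // mu > t: chi-based rejection on (0, t]
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  }
  return x;
}

// One draw from PG(1, c)
static double rpg1(double c) {
  double z = std::fabs(c) * 0.5;
  double K = PI2_8 + 0.5 * z * z;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  double ratio = p / (p + q);

  for (;;) {
    double x;
    if (R::unif_rand() < ratio) {
      x = TRUNC + R::exp_rand() / K;      // exponential tail beyond t
    } else {
      x = rtigauss(z, TRUNC);             // truncated inverse-Gaussian body
    }
    double s = acoef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= acoef(n, x);
        if (y <= s) return 0.25 * x;      // accept
      } else {
        s += acoef(n, x);
        if (y > s) break;                 // reject, repropose
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(IntegerVector b, NumericVector c) {
  R_xlen_t n = b.size();
  if (c.size() != n) stop("b and c must have equal length");
  NumericVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    int bi = b[i];
    if (bi < 1) stop("PG exposure b must be a positive integer");
    double acc = 0.0;
    for (int k = 0; k < bi; ++k) acc += rpg1(c[i]);
    out[i] = acc;
  }
  return out;
}
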