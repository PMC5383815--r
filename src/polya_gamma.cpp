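// Polya-Gamma PG(1, z) sampling by Devroye's alternating-series method.
//
// A PG(1, z) variate equals J*(1, z/2) / 4, where J* is the tilted Jacobi
// distribution. J*(1, h) is sampled exactly by an accept-reject scheme whose
// proposal is a two-piece mixture -- a truncated inverse-Gaussian body on
// (0, t] and an exponential tail on (t, inf) -- and whose acceptance test
// evaluates the alternating series expansion of the Jacobi density until it
// brackets the uniform draw. Uses R's RNG, so draws are reproducible under
// set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;               // series switch point t
static const double PI2_8 = M_PI * M_PI / 8.0;

// n-th alternating-series coefficient of the J*(1, 0) density at x
static double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x <= TRUNC) {
    return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * np * np / x);
  }
  return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
}

// CDF of the inverse Gaussian IG(mu, lambda = 1) at x; mu = inf handled
static double pigauss(double x, double mu) {
  double rx = 1.0 / std::sqrt(x);
  double z = (mu == R_PosInf) ? 0.0 : x / mu;
  return R::pnorm(rx * (z - 1.0), 0.0, 1.0, 1, 0) +
         std::exp((mu == R_PosInf) ? 0.0 : 2.0 / mu) *
           R::pnorm(-rx * (z + 1.0), 0.0, 1.0, 1, 0);
}

// Inverse-Gaussian IG(mu, 1) truncated to (0, TRUNC]; h = 1/mu >= 0
static double rtigauss(double h) {
  double mu = (h > 1e-12) ? 1.0 / h : R_PosInf;
  double x;
  if (mu == R_PosInf || mu > TRUNC) {
    // drift negligible relative to the truncation: one-sided chi-square
    // proposal for 1/X, thinned by the drift term exp(-h^2 x / 2)
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      if (h <= 1e-12 || R::unif_rand() <= std::exp(-0.5 * h * h * x)) break;
    }
  } else {
    // standard IG transform sampler, redrawn until inside the truncation
    do {
      double y = R::norm_rand();
      y = y * y;
      x = mu + 0.5 * mu * mu * y -
          0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    } while (x > TRUNC);
  }
  return x;
}

// One J*(1, h) draw, h >= 0
static double rjacobi(double h) {
  double lambda = PI2_8 + 0.5 * h * h;
  double p = M_PI / (2.0 * lambda) * std::exp(-lambda * TRUNC);
  double q = 2.0 * std::exp(-h) *
             pigauss(TRUNC, (h > 1e-12) ? 1.0 / h : R_PosInf);
  double ratio = p / (p + q);
  for (;;) {
    double x;
    if (R::unif_rand() < ratio) {
      x = TRUNC + R::exp_rand() / lambda;     // exponential tail
    } else {
      x = rtigauss(h);                        // truncated IG body
    }
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    for (int n = 1;; ++n) {
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x;                 // accepted
      } else {
        s += a_coef(n, x);
        if (y > s) break;                     // rejected: new proposal
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector rpg_devroye(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double h = std::fabs(z[i]) * 0.5;
    out[i] = 0.25 * rjacobi(h);
  }
  return out;
}
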