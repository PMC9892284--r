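#include <Rcpp.h>
#include "lnbart.h"

// Polya-gamma PG(b, z) sampling.
//
// PG(1, z) uses the exact alternating-series acceptance-rejection sampler
// (Devroye-type) on the Jacobi J*(1, z/2) scale; integer b <= threshold is
// drawn by composition, larger b by a moment-matched gamma whose first two
// moments equal the exact PG(b, z) moments.  All randomness comes from R's
// generator so draws are reproducible under set.seed().

static const double TRUNC = 0.64;

// cdf at t of inverse-Gaussian(mu = 1/z, lambda = 1); z = 0 is the Levy limit
static double pigauss(double t, double z) {
  double s = 1.0 / std::sqrt(t);
  if (z <= 0.0)
    return 2.0 * R::pnorm(-s, 0.0, 1.0, 1, 0);
  return R::pnorm(s * (t * z - 1.0), 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z + R::pnorm(-s * (t * z + 1.0), 0.0, 1.0, 1, 1));
}

// coefficients of the alternating series for the J*(1, z) density
static double a_coef(int n, double x) {
  double d = n + 0.5;
  if (x <= TRUNC)
    return M_PI * d * std::pow(2.0 / (M_PI * x), 1.5) * std::exp(-2.0 * d * d / x);
  return M_PI * d * std::exp(-0.5 * d * d * M_PI * M_PI * x);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC]
static double rtigauss(double z) {
  double t = TRUNC;
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  double X;
  if (mu > t) {
    // rejection against a truncated inverse-chi-square proposal
    for (;;) {
      double E, Ep;
      do {
        E = R::exp_rand();
        Ep = R::exp_rand();
      } while (E * E > 2.0 * Ep / t);
      double den = 1.0 + t * E;
      X = t / (den * den);
      double alpha = (z > 0.0) ? std::exp(-0.5 * z * z * X) : 1.0;
      if (R::unif_rand() <= alpha) return X;
    }
  }
  X = t + 1.0;
  while (X > t) {
    double Y = R::norm_rand();
    Y = Y * Y;
    double muY = mu * Y;
    X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
    if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
  }
  return X;
}

// one exact PG(1, z) draw
double pg1_draw(double zin) {
  double z = std::fabs(zin) * 0.5;
  double K = M_PI * M_PI * 0.125 + 0.5 * z * z;
  double p_right = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double p_left = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  double frac = p_right / (p_right + p_left);
  for (;;) {
    double X;
    if (R::unif_rand() < frac)
      X = TRUNC + R::exp_rand() / K;   // exponential tail beyond TRUNC
    else
      X = rtigauss(z);                 // inverse-Gaussian body below TRUNC
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    for (int n = 1;; ++n) {
      if (n & 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
  }
}

double pg_mean(double b, double z) {
  z = std::fabs(z);
  if (z < 1e-12) return b * 0.25;
  return b * std::tanh(0.5 * z) / (2.0 * z);
}

double pg_var(double b, double z) {
  z = std::fabs(z);
  if (z < 1e-4) return b / 24.0;
  double ch = std::cosh(0.5 * z);
  return b * (std::sinh(z) - z) / (4.0 * z * z * z * ch * ch);
}

// PG(b, z): exact composition for integer b up to threshold, otherwise a
// gamma with the exact mean and variance (CLT regime).
double pg_draw_one(double b, double z, int threshold) {
  if (b <= 0.0) Rcpp::stop("PG shape parameter b must be positive");
  if (b == std::floor(b) && b <= (double)threshold) {
    int bi = (int)b;
    double s = 0.0;
    for (int i = 0; i < bi; ++i) s += pg1_draw(z);
    return s;
  }
  double m = pg_mean(b, z), v = pg_var(b, z);
  double shape = m * m / v, scale = v / m;
  return R::rgamma(shape, scale);
}

//' @noRd
// [[Rcpp::export(name = ".pg_draw_cpp")]]
Rcpp::NumericVector pg_draw_cpp(int n, double b, double z, int threshold) {
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pg_draw_one(b, z, threshold);
  return out;
}
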