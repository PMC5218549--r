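#include <Rcpp.h>
using namespace Rcpp;

// Standard-normal draw truncated to (a, +inf). Inverse CDF on the upper tail
// keeps precision for moderate a; far tails (a > 6) switch to the
// exponential-rejection sampler of Robert (1995), which stays exact where the
// inverse CDF underflows.
static double rtnorm_std_lower(double a) {
  if (a <= 6.0) {
    double tail = R::pnorm(a, 0.0, 1.0, 0, 0);  // P(z > a)
    double u = unif_rand();
    return R::qnorm((1.0 - u) * tail, 0.0, 1.0, 0, 0);
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + exp_rand() / alpha;
    double d = z - alpha;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return z;
  }
}

static double rtnorm_lower(double mean, double sd, double lo) {
  return mean + sd * rtnorm_std_lower((lo - mean) / sd);
}

static double rtnorm_upper(double mean, double sd, double hi) {
  // z < b equals -z > -b by symmetry
  return mean - sd * rtnorm_std_lower((mean - hi) / sd);
}

// One single-site Gibbs sweep over the latent utilities y* of a SAR probit.
//
// The joint latent distribution is N(mu, H^{-1}) with precision
// H = (I - rho W)'(I - rho W) and H mu = (I - rho W)' X beta = b.
// The full conditional of y*_i is
//   N( y*_i - r_i / H_ii , 1 / H_ii ),   r = H y* - b,
// truncated to (0, inf) when y_i = 1 and (-inf, 0] when y_i = 0.
// H is passed in compressed sparse column form (symmetric, so columns are
// rows); r is maintained incrementally as sites update.
//
// [[Rcpp::export]]
NumericVector gibbs_latent_sweep(IntegerVector Hp, IntegerVector Hi,
                                 NumericVector Hx, NumericVector b,
                                 NumericVector ystar, IntegerVector y,
                                 int n_sweeps = 1) {
  int n = ystar.size();
  NumericVector ys = clone(ystar);
  // r = H ys - b
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = -b[i];
  for (int j = 0; j < n; ++j) {
    double v = ys[j];
    for (int k = Hp[j]; k < Hp[j + 1]; ++k) r[Hi[k]] += Hx[k] * v;
  }
  // locate diagonal entries once
  std::vector<int> dpos(n, -1);
  for (int j = 0; j < n; ++j) {
    for (int k = Hp[j]; k < Hp[j + 1]; ++k) {
      if (Hi[k] == j) { dpos[j] = k; break; }
    }
  }
  RNGScope scope;
  for (int s = 0; s < n_sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      double hii = Hx[dpos[i]];
      double m = ys[i] - r[i] / hii;
      double sd = 1.0 / std::sqrt(hii);
      if (!std::isfinite(m)) stop("non-finite conditional mean in latent sweep");
      double draw = (y[i] == 1) ? rtnorm_lower(m, sd, 0.0)
                                : rtnorm_upper(m, sd, 0.0);
      double delta = draw - ys[i];
      if (delta != 0.0) {
        ys[i] = draw;
        for (int k = Hp[i]; k < Hp[i + 1]; ++k) r[Hi[k]] += Hx[k] * delta;
      }
    }
  }
  return ys;
}
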