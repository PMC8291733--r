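#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One draw from N(mean, sd^2) truncated to [0, inf), using R's RNG.
// Plain rejection from the normal when the acceptance rate is decent;
// Robert (1995) exponential rejection when the untruncated mass below
// zero dominates.
static double rtnorm_pos(double mean, double sd) {
  double alpha = -mean / sd; // standardized lower bound
  if (alpha < 0.45) {
    for (;;) {
      double z = norm_rand();
      if (z >= alpha) return mean + sd * z;
    }
  }
  // exponential proposal shifted to alpha
  double lam = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (;;) {
    double z = alpha + exp_rand() / lam;
    double d = z - lam;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return mean + sd * z;
  }
}

// Gibbs sampler for the truncated multivariate normal on the non-negative
// orthant, density prop to exp{-(x-mu)' K (x-mu)/2} on [0,inf)^m.
// Coordinate conditionals are univariate normals truncated to [0,inf).
// [[Rcpp::export]]
arma::mat gibbs_tnorm_cpp(int n, const arma::mat& K, const arma::vec& mu,
                          int burnin, int thin) {
  const int m = K.n_rows;
  arma::mat out(n, m);
  arma::vec x = arma::clamp(mu, 0.0, arma::datum::inf); // start at projected mean
  for (int j = 0; j < m; ++j) if (x[j] <= 0.0) x[j] = 1e-8;
  arma::vec sd(m);
  for (int j = 0; j < m; ++j) sd[j] = 1.0 / std::sqrt(K(j, j));
  int kept = 0, it = 0;
  while (kept < n) {
    for (int j = 0; j < m; ++j) {
      double s = arma::dot(K.col(j), x - mu) - K(j, j) * (x[j] - mu[j]);
      double cmean = mu[j] - s / K(j, j);
      x[j] = rtnorm_pos(cmean, sd[j]);
    }
    ++it;
    if (it > burnin && ((it - burnin) % thin == 0)) {
      out.row(kept) = x.t();
      ++kept;
    }
  }
  return out;
}

// log conditional density (up to a constant) of coordinate j in the
// pairwise interaction power model:
//   f(x) = -kjj x^{2a}/(2a) - x^a * s + eta * (x^b - 1)/b      (b > 0)
//   f(x) = -kjj x^{2a}/(2a) - x^a * s + eta * log(x)           (b = 0)
// with s = sum_{k != j} k_{jk} x_k^a.
static double cond_logdens(double x, double a, double b, double kjj,
                           double s, double eta, bool centered) {
  double xa = std::pow(x, a);
  double v = -kjj * xa * xa / (2.0 * a) - xa * s;
  if (!centered) {
    if (b == 0.0) v += eta * std::log(x);
    else v += eta * (std::pow(x, b) - 1.0) / b;
  }
  return v;
}

// Slice sampler step (Neal 2003, stepping out + shrinkage) on (0, inf).
static double slice_step(double x0, double a, double b, double kjj,
                         double s, double eta, bool centered) {
  double f0 = cond_logdens(x0, a, b, kjj, s, eta, centered);
  double y = f0 - exp_rand(); // log slice level
  double w = std::max(x0, 0.25);
  double u = unif_rand();
  double L = x0 - u * w, R = L + w;
  // step out; the left end never crosses 0 (density support is x > 0)
  int steps = 50;
  while (L > 0.0 && steps-- > 0 &&
         cond_logdens(L, a, b, kjj, s, eta, centered) > y) L -= w;
  if (L < 0.0) L = 0.0;
  steps = 50;
  while (steps-- > 0 && cond_logdens(R, a, b, kjj, s, eta, centered) > y) R += w;
  // shrinkage
  for (int i = 0; i < 200; ++i) {
    double x1 = L + unif_rand() * (R - L);
    if (x1 > 0.0 && cond_logdens(x1, a, b, kjj, s, eta, centered) > y) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0; // numerically stuck; keep current state
}

// Gibbs sampler for pairwise interaction power models on the orthant.
// [[Rcpp::export]]
arma::mat gibbs_power_cpp(int n, double a, double b, const arma::mat& K,
                          const arma::vec& eta, bool centered,
                          int burnin, int thin) {
  const int m = K.n_rows;
  arma::mat out(n, m);
  arma::vec x(m, arma::fill::ones);
  arma::vec xa = arma::pow(x, a);
  int kept = 0, it = 0;
  while (kept < n) {
    for (int j = 0; j < m; ++j) {
      double s = arma::dot(K.col(j), xa) - K(j, j) * xa[j];
      x[j] = slice_step(x[j], a, b, K(j, j), s,
                        centered ? 0.0 : eta[j], centered);
      xa[j] = std::pow(x[j], a);
    }
    ++it;
    if (it > burnin && ((it - burnin) % thin == 0)) {
      out.row(kept) = x.t();
      ++kept;
    }
  }
  return out;
}
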