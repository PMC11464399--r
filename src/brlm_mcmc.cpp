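// Posterior sampler for the Bayesian relevant life-course exposure model.
//
// Parameter vector theta (length d = 2 + (K-1) + P [+ 1]):
//   theta[0]            alpha        intercept
//   theta[1]            beta_life    lifetime effect (log-RR or beta)
//   theta[2..K]         z            additive-log-ratio logits of the
//                                    K-simplex weights (last logit fixed 0)
//   theta[K+1..K+P]     gamma        covariate effects
//   theta[d-1]          log(sigma)   gaussian family only
//
// Priors: alpha, gamma ~ Normal(0, prior_sd); beta_life ~ Cauchy(0, beta_scale);
// w ~ Dirichlet(conc) (with the ALR Jacobian prod_k w_k on the logit scale);
// sigma ~ half-Cauchy(0, 2.5) (with the log-scale Jacobian sigma).
//
// Families: 0 = relative_risk (Poisson likelihood on 0/1 outcomes, log link —
// the "Poisson trick" giving relative risks), 1 = gaussian, 2 = log-link
// Bernoulli (sensitivity variant; linear predictor must stay negative).
//
// Sampling: adaptive random-walk Metropolis. During warmup the proposal is a
// scaled empirical-covariance Gaussian (Haario-style adaptation) with a
// Robbins-Monro global scale targeting ~23% acceptance; after warmup the
// kernel is frozen and draws are thinned heavily, so retained draws are
// nearly independent. R's RNG is used throughout, so set.seed() at the R
// level makes chains reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void theta_to_weights(const arma::vec& th, int K, arma::vec& w) {
  arma::vec z(K);
  for (int k = 0; k < K - 1; ++k) z(k) = th(2 + k);
  z(K - 1) = 0.0;
  double m = z.max();
  w = arma::exp(z - m);
  w /= arma::accu(w);
}

static double log_post(const arma::vec& th, const arma::mat& X,
                       const arma::mat& C, const arma::vec& y, int family,
                       int K, int P, double prior_sd, double beta_scale,
                       const arma::vec& conc, bool prior_only) {
  const double alpha = th(0), beta = th(1);
  arma::vec w;
  theta_to_weights(th, K, w);

  double lp = -0.5 * alpha * alpha / (prior_sd * prior_sd);
  const double bs = beta / beta_scale;
  lp += -std::log1p(bs * bs);  // Cauchy(0, beta_scale) kernel
  // Dirichlet(conc) density on w plus ALR-transform Jacobian prod_k w_k:
  // sum_k (conc_k - 1) log w_k + sum_k log w_k = sum_k conc_k log w_k
  for (int k = 0; k < K; ++k) lp += conc(k) * std::log(w(k));

  int idx = 2 + (K - 1);
  arma::vec gamma;
  if (P > 0) {
    gamma = th.subvec(idx, idx + P - 1);
    lp += -0.5 * arma::dot(gamma, gamma) / (prior_sd * prior_sd);
    idx += P;
  }
  double sigma = 1.0;
  if (family == 1) {
    const double ls = th(idx);
    sigma = std::exp(ls);
    const double ss = sigma / 2.5;
    lp += -std::log1p(ss * ss) + ls;  // half-Cauchy + log-scale Jacobian
  }
  if (prior_only) return lp;

  arma::vec eta = alpha + beta * (X * w);
  if (P > 0) eta += C * gamma;
  if (family == 0) {
    // Poisson trick on 0/1 outcomes: sum y*eta - exp(eta)
    lp += arma::dot(y, eta) - arma::accu(arma::exp(eta));
  } else if (family == 1) {
    const double n = static_cast<double>(y.n_elem);
    arma::vec r = y - eta;
    lp += -n * std::log(sigma) - 0.5 * arma::dot(r, r) / (sigma * sigma);
  } else {
    if (eta.max() >= 0.0) return -arma::datum::inf;  // risk must stay < 1
    for (arma::uword i = 0; i < y.n_elem; ++i) {
      lp += (y(i) > 0.5) ? eta(i) : std::log(-std::expm1(eta(i)));
    }
  }
  return lp;
}

// [[Rcpp::export(name = ".brlm_chain")]]
arma::mat brlm_chain(const arma::mat& X, const arma::mat& C,
                     const arma::vec& y, int family, const arma::vec& conc,
                     double prior_sd, double beta_scale, int warmup, int iter,
                     int thin, const arma::vec& init, bool prior_only) {
  const int K = X.n_cols;
  const int P = C.n_cols;
  const int d = init.n_elem;
  const int n_keep = iter / thin;

  arma::vec th = init;
  double lp = log_post(th, X, C, y, family, K, P, prior_sd, beta_scale, conc,
                       prior_only);
  if (!std::isfinite(lp)) stop("sampler error: initial state has zero posterior density");

  arma::mat hist(warmup, d, arma::fill::zeros);
  arma::mat chol_prop = 0.1 * arma::eye(d, d);
  double log_scale = 0.0;
  const double target_acc = 0.234;

  arma::mat out(n_keep, d);
  arma::vec prop(d), z(d);
  int kept = 0;

  for (int t = 0; t < warmup + iter; ++t) {
    for (int j = 0; j < d; ++j) z(j) = R::norm_rand();
    prop = th + std::exp(log_scale) * (chol_prop.t() * z);
    double lp_prop = log_post(prop, X, C, y, family, K, P, prior_sd,
                              beta_scale, conc, prior_only);
    double acc = std::exp(std::min(0.0, lp_prop - lp));
    if (R::unif_rand() < acc) { th = prop; lp = lp_prop; }

    if (t < warmup) {
      hist.row(t) = th.t();
      log_scale += (acc - target_acc) / std::sqrt(1.0 + t / 10.0);
      if (t >= 199 && (t + 1) % 100 == 0) {
        arma::mat cv = arma::cov(hist.rows(0, t));
        cv = (2.38 * 2.38 / d) * cv + 1e-8 * arma::eye(d, d);
        arma::mat ch;
        if (arma::chol(ch, cv)) chol_prop = ch;
      }
      if (t == warmup - 1) log_scale = std::min(log_scale, 1.0);
    } else {
      int s = t - warmup;
      if ((s + 1) % thin == 0 && kept < n_keep) out.row(kept++) = th.t();
    }
  }
  return out.rows(0, kept - 1);
}
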