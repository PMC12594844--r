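// Core numerics for the Marshall-Olkin bivariate inverse Weibull model:
// ranked-set / simple-random-sample log-likelihood, analytic score and
// observed-information Hessian, Newton-Raphson fitting in log-parameter
// space, and a Metropolis-within-Gibbs sampler. All randomness goes through
// R's RNG so set.seed() governs every draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log(1 - exp(-a)) for a > 0, stable for both tiny and large a.
static inline double log_one_minus_exp(double a) {
  if (a <= 0.0) return R_NegInf;
  if (a < M_LN2) return std::log(-std::expm1(-a));
  return std::log1p(-std::exp(-a));
}

struct BiwData {
  arma::vec x, y, lx, ly;
  arma::ivec d1, d2, d3, rnk;
  int m;        // set size (1 for SRS)
  int n;
};

static BiwData make_data(const arma::vec& x, const arma::vec& y,
                         const arma::ivec& d1, const arma::ivec& d2,
                         const arma::ivec& d3, const arma::ivec& rnk, int m) {
  BiwData d;
  d.x = x; d.y = y; d.d1 = d1; d.d2 = d2; d.d3 = d3; d.rnk = rnk; d.m = m;
  d.n = x.n_elem;
  d.lx = arma::log(x); d.ly = arma::log(y);
  return d;
}

// Log-likelihood. Branch densities follow the joint pdf of the model
// (the x>y branch uses exp(-lam1 x^-a - lam23 y^-a), i.e. the form
// consistent with the joint cdf); each observation at rank i in a set of
// size m additionally contributes (i-1) log F(x) + (m-i) log(1-F(x)) with
// F the IW(alpha, lam13) marginal cdf of the ranking variable.
static double loglik_core(const BiwData& d, double alpha, double l1,
                          double l2, double l3) {
  if (!(alpha > 0.0) || !(l1 > 0.0) || !(l2 > 0.0) || l3 < 0.0)
    return R_NegInf;
  const double l13 = l1 + l3, l23 = l2 + l3, l123 = l1 + l2 + l3;
  const double la = std::log(alpha);
  const double ll1 = std::log(l1), ll2 = std::log(l2);
  const double ll3 = l3 > 0.0 ? std::log(l3) : R_NegInf;
  const double ll13 = std::log(l13), ll23 = std::log(l23);
  double ll = 0.0;
  for (int i = 0; i < d.n; ++i) {
    const double lx = d.lx[i], ly = d.ly[i];
    const double X = std::exp(-alpha * lx);
    const double Y = std::exp(-alpha * ly);
    const double c = d.d1[i] + d.rnk[i] - 1;   // lam13 coefficient on X
    const int v = d.m - d.rnk[i];
    if (d.d1[i]) {
      ll += ll13 + ll2 + 2.0 * la - (alpha + 1.0) * (lx + ly) - l2 * Y;
    } else if (d.d2[i]) {
      ll += ll1 + ll23 + 2.0 * la - (alpha + 1.0) * (lx + ly) - l1 * X - l23 * Y;
    } else {
      if (l3 <= 0.0) return R_NegInf;  // diagonal observation needs lam3 > 0
      ll += ll3 + la - (alpha + 1.0) * lx - l123 * X;
    }
    ll -= l13 * c * X;
    if (v > 0) ll += v * log_one_minus_exp(l13 * X);
    if (!std::isfinite(ll)) return R_NegInf;
  }
  return ll;
}

// Analytic gradient and Hessian in the natural parameters, order
// (alpha, lam1, lam2, lam3). Re-derived from the implemented
// log-likelihood; verified against finite differences in the tests.
static void score_hessian_core(const BiwData& d, double alpha, double l1,
                               double l2, double l3, arma::vec& g,
                               arma::mat& H) {
  const double l13 = l1 + l3, l23 = l2 + l3, l123 = l1 + l2 + l3;
  g.zeros(4); H.zeros(4, 4);
  for (int i = 0; i < d.n; ++i) {
    const double lx = d.lx[i], ly = d.ly[i];
    const double X = std::exp(-alpha * lx);
    const double Y = std::exp(-alpha * ly);
    const int D1 = d.d1[i], D2 = d.d2[i], D3 = d.d3[i];
    const double c = D1 + d.rnk[i] - 1;
    const int v = d.m - d.rnk[i];
    // R = u/(1-u) with u = exp(-lam13 X); E = d(X R)/d alpha
    double R = 0.0, E = 0.0, XXR = 0.0;
    if (v > 0) {
      const double a = l13 * X;
      const double om = -std::expm1(-a);           // 1 - u
      R = std::exp(-a) / om;
      XXR = X * X * R * (1.0 + R);
      E = X * lx * R * (a * (1.0 + R) - 1.0);
    }
    g[0] += (2.0 * (D1 + D2) + D3) / alpha
          - ((D1 + D2 + D3) * lx + (D1 + D2) * ly)
          + l13 * c * X * lx + l2 * D1 * Y * ly + l1 * D2 * X * lx
          + l23 * D2 * Y * ly + l123 * D3 * X * lx
          - v * l13 * X * lx * R;
    g[1] += D1 / l13 + D2 / l1 - (c + D2 + D3) * X + v * X * R;
    g[2] += D1 / l2 + D2 / l23 - (D1 + D2) * Y - D3 * X;
    g[3] += D1 / l13 + D2 / l23 + (D3 > 0 ? D3 / l3 : 0.0)
          - (c + D3) * X - D2 * Y + v * X * R;

    H(0, 0) += -(2.0 * (D1 + D2) + D3) / (alpha * alpha)
             - l13 * c * X * lx * lx - l2 * D1 * Y * ly * ly
             - l1 * D2 * X * lx * lx - l23 * D2 * Y * ly * ly
             - l123 * D3 * X * lx * lx - v * l13 * lx * E;
    H(0, 1) += (c + D2 + D3) * X * lx + v * E;
    H(0, 2) += (D1 + D2) * Y * ly + D3 * X * lx;
    H(0, 3) += (c + D3) * X * lx + D2 * Y * ly + v * E;
    H(1, 1) += -D1 / (l13 * l13) - D2 / (l1 * l1) - v * XXR;
    H(1, 3) += -D1 / (l13 * l13) - v * XXR;
    H(2, 2) += -D1 / (l2 * l2) - D2 / (l23 * l23);
    H(2, 3) += -D2 / (l23 * l23);
    H(3, 3) += -D1 / (l13 * l13) - D2 / (l23 * l23)
             - (D3 > 0 ? D3 / (l3 * l3) : 0.0) - v * XXR;
  }
  H(1, 0) = H(0, 1); H(2, 0) = H(0, 2); H(3, 0) = H(0, 3);
  H(3, 1) = H(1, 3); H(2, 1) = H(1, 2); H(3, 2) = H(2, 3);
}

// [[Rcpp::export]]
double cpp_loglik(const arma::vec& x, const arma::vec& y,
                  const arma::ivec& d1, const arma::ivec& d2,
                  const arma::ivec& d3, const arma::ivec& rnk, int m,
                  double alpha, double l1, double l2, double l3) {
  BiwData d = make_data(x, y, d1, d2, d3, rnk, m);
  return loglik_core(d, alpha, l1, l2, l3);
}

// [[Rcpp::export]]
List cpp_score_hessian(const arma::vec& x, const arma::vec& y,
                       const arma::ivec& d1, const arma::ivec& d2,
                       const arma::ivec& d3, const arma::ivec& rnk, int m,
                       double alpha, double l1, double l2, double l3) {
  BiwData d = make_data(x, y, d1, d2, d3, rnk, m);
  arma::vec g; arma::mat H;
  score_hessian_core(d, alpha, l1, l2, l3, g, H);
  return List::create(_["score"] = g, _["hessian"] = H);
}

// Newton-Raphson on (log alpha, log lam1, log lam2, log lam3) with
// step-halving whenever the log-likelihood would decrease. Convergence:
// max |change in natural parameters| < tol. The reported vcov is the
// inverse of the negative Hessian (observed information) in the natural
// parameters at the accepted optimum.
// [[Rcpp::export]]
List cpp_fit_mle(const arma::vec& x, const arma::vec& y,
                 const arma::ivec& d1, const arma::ivec& d2,
                 const arma::ivec& d3, const arma::ivec& rnk, int m,
                 const arma::vec& init, int max_iter = 200,
                 double tol = 1e-6, int max_halvings = 30) {
  BiwData d = make_data(x, y, d1, d2, d3, rnk, m);
  arma::vec theta = arma::log(init);          // log parameters
  theta = arma::clamp(theta, -18.0, 18.0);
  arma::vec psi = arma::exp(theta);
  double ll = loglik_core(d, psi[0], psi[1], psi[2], psi[3]);
  if (!std::isfinite(ll)) {
    theta.zeros(); psi.ones();
    ll = loglik_core(d, 1.0, 1.0, 1.0, 1.0);
  }
  arma::vec g(4); arma::mat H(4, 4);
  bool converged = false, singular = false;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    score_hessian_core(d, psi[0], psi[1], psi[2], psi[3], g, H);
    arma::vec gt = g % psi;                   // chain rule to log scale
    arma::mat Ht = (H % (psi * psi.t()));
    Ht.diag() += gt;
    arma::vec step;
    bool ok = arma::solve(step, Ht, -gt, arma::solve_opts::no_approx);
    if (!ok || !step.is_finite()) {
      singular = true;
      step = arma::pinv(Ht) * (-gt);
      if (!step.is_finite()) step = gt / std::max(1.0, arma::norm(gt, "inf"));
    }
    // cap absurd steps so exp() cannot overflow
    double smax = arma::norm(step, "inf");
    if (smax > 5.0) step *= 5.0 / smax;
    double t = 1.0;
    double ll_new = R_NegInf;
    arma::vec theta_new, psi_new;
    bool improved = false;
    for (int h = 0; h <= max_halvings; ++h) {
      theta_new = arma::clamp(theta + t * step, -18.0, 18.0);
      psi_new = arma::exp(theta_new);
      ll_new = loglik_core(d, psi_new[0], psi_new[1], psi_new[2], psi_new[3]);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) { improved = true; break; }
      t *= 0.5;
    }
    if (!improved) break;                     // cannot ascend: stop here
    double dmax = arma::norm(psi_new - psi, "inf");
    theta = theta_new; psi = psi_new; ll = ll_new;
    if (dmax < tol) { converged = true; ++iter; break; }
  }
  score_hessian_core(d, psi[0], psi[1], psi[2], psi[3], g, H);
  double gnorm = arma::norm(g % psi, "inf");
  if (!converged && gnorm < 1e-5 * std::max(1.0, std::abs(ll)))
    converged = true;                         // flat optimum: accept
  if (arma::norm(theta, "inf") >= 17.99)
    converged = false;                        // ran into the domain clamp
  arma::mat vcov(4, 4);
  bool vok = arma::inv_sympd(vcov, arma::symmatu(-H));
  if (!vok) {
    vok = arma::inv(vcov, -H);
    if (!vok) { vcov = arma::pinv(arma::symmatu(-H)); singular = true; }
  }
  return List::create(
    _["estimates"] = psi, _["loglik"] = ll, _["converged"] = converged,
    _["iterations"] = iter, _["gradient_norm"] = gnorm,
    _["vcov"] = arma::symmatu(vcov), _["singular"] = singular);
}

// Metropolis-within-Gibbs with Gaussian random walks on each log
// parameter. Target: prior x likelihood (gamma priors on the rates, gamma
// prior on alpha when alpha is sampled) with the log-scale Jacobian.
// Proposal scales adapt toward `target_acc` during burn-in only.
// [[Rcpp::export]]
List cpp_mcmc(const arma::vec& x, const arma::vec& y,
              const arma::ivec& d1, const arma::ivec& d2,
              const arma::ivec& d3, const arma::ivec& rnk, int m,
              const arma::vec& prior_shape, const arma::vec& prior_rate,
              double alpha_shape, double alpha_rate,
              bool alpha_fixed, double alpha_value,
              const arma::vec& init, int iter, int burnin,
              double target_acc = 0.3) {
  BiwData d = make_data(x, y, d1, d2, d3, rnk, m);
  RNGScope scope;
  arma::vec theta = arma::clamp(arma::log(init), -9.5, 9.5);
  if (alpha_fixed) theta[0] = std::log(alpha_value);
  // log posterior of theta = log-parameters (includes Jacobian sum(theta))
  auto lpost = [&](const arma::vec& th) {
    arma::vec p = arma::exp(th);
    double lp = loglik_core(d, p[0], p[1], p[2], p[3]);
    if (!std::isfinite(lp)) return R_NegInf;
    for (int j = 0; j < 3; ++j)
      lp += prior_shape[j] * th[j + 1] - prior_rate[j] * p[j + 1];
    if (!alpha_fixed) lp += alpha_shape * th[0] - alpha_rate * p[0];
    else lp += 0.0;
    return lp;  // Jacobian absorbed: (a-1)log p + log p = a log p = a*th
  };
  double cur = lpost(theta);
  if (!std::isfinite(cur)) { theta.zeros(); if (alpha_fixed) theta[0] = std::log(alpha_value); cur = lpost(theta); }
  arma::vec scales(4, arma::fill::value(0.4));
  arma::mat chain(iter, 4);
  arma::vec acc(4, arma::fill::zeros), tries(4, arma::fill::zeros);
  arma::vec acc_win(4, arma::fill::zeros), try_win(4, arma::fill::zeros);
  const int first = alpha_fixed ? 1 : 0;
  for (int it = 0; it < iter; ++it) {
    for (int j = first; j < 4; ++j) {
      arma::vec prop = theta;
      prop[j] += scales[j] * norm_rand();
      if (std::abs(prop[j]) > 20.0) { try_win[j] += 1; if (it >= burnin) tries[j] += 1; continue; }
      double lp = lpost(prop);
      bool accept = std::isfinite(lp) &&
        (lp - cur >= 0.0 || unif_rand() < std::exp(lp - cur));
      if (accept) { theta = prop; cur = lp; acc_win[j] += 1; if (it >= burnin) acc[j] += 1; }
      try_win[j] += 1;
      if (it >= burnin) tries[j] += 1;
    }
    // adapt during burn-in, every 50 sweeps; frozen afterwards
    if (it < burnin && (it + 1) % 50 == 0) {
      for (int j = first; j < 4; ++j) {
        if (try_win[j] > 0) {
          double r = acc_win[j] / try_win[j];
          scales[j] *= std::exp(1.5 * (r - target_acc));
          scales[j] = std::min(std::max(scales[j], 1e-3), 10.0);
        }
        acc_win[j] = 0; try_win[j] = 0;
      }
    }
    chain.row(it) = arma::exp(theta).t();
  }
  arma::vec rate(4);
  for (int j = 0; j < 4; ++j)
    rate[j] = tries[j] > 0 ? acc[j] / tries[j] : NA_REAL;
  return List::create(_["chain"] = chain, _["acceptance"] = rate,
                      _["scales"] = scales);
}
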