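#include <Rcpp.h>
using namespace Rcpp;

// Skew-normal log-density with location mu, scale sigma (> 0) and shape alpha:
//   log f(x) = log 2 - log sigma + log phi(z) + log Phi(alpha * z),  z = (x - mu)/sigma
// phi / Phi are the standard normal pdf / cdf.
// [[Rcpp::export]]
NumericVector dskewnorm_cpp(NumericVector x, double mu, double sigma,
                            double alpha, bool log_p) {
  const int n = x.size();
  NumericVector out(n);
  const double l2 = M_LN2 - std::log(sigma);
  for (int i = 0; i < n; ++i) {
    const double z = (x[i] - mu) / sigma;
    const double v = l2 + R::dnorm(z, 0.0, 1.0, 1) + R::pnorm(alpha * z, 0.0, 1.0, 1, 1);
    out[i] = log_p ? v : std::exp(v);
  }
  return out;
}

static double sn_loglik(const NumericVector &x, double mu, double sigma,
                        double alpha) {
  const int n = x.size();
  const double l2 = M_LN2 - std::log(sigma);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double z = (x[i] - mu) / sigma;
    ll += l2 + R::dnorm(z, 0.0, 1.0, 1) + R::pnorm(alpha * z, 0.0, 1.0, 1, 1);
  }
  return ll;
}

// [[Rcpp::export]]
double snll_cpp(NumericVector x, double mu, double sigma, double alpha) {
  if (sigma <= 0.0) return R_NegInf;
  return sn_loglik(x, mu, sigma, alpha);
}

// Log-posterior on the unconstrained scale theta = (mu, log sigma, alpha).
// Priors: mu ~ Normal(dbar, prior_mu_sd); sigma ~ half-Cauchy(beta);
// alpha ~ Normal(0, prior_alpha_sd).  Includes the log-Jacobian of
// sigma = exp(log sigma).
static double sn_logpost(const NumericVector &x, double mu, double lsigma,
                         double alpha, double dbar, double prior_mu_sd,
                         double beta, double prior_alpha_sd) {
  const double sigma = std::exp(lsigma);
  double lp = sn_loglik(x, mu, sigma, alpha);
  lp += R::dnorm(mu, dbar, prior_mu_sd, 1);
  lp += -std::log1p((sigma / beta) * (sigma / beta)); // half-Cauchy kernel
  lp += R::dnorm(alpha, 0.0, prior_alpha_sd, 1);
  lp += lsigma; // Jacobian
  return lp;
}

// Adaptive random-walk Metropolis for the 3-parameter skew-normal posterior.
// Proposal covariance adapts to the running empirical covariance of the chain
// during warmup (scaled 2.38^2/3) with a Robbins-Monro global scale targeting
// acceptance ~0.3; frozen after warmup so kept draws are a valid Markov chain.
// Uses R's RNG: seeding via set.seed() on the R side.
// [[Rcpp::export]]
List sn_mcmc_cpp(NumericVector x, int n_chains, int warmup, int iter,
                 double prior_mu_sd, double prior_sigma_beta,
                 double prior_alpha_sd) {
  RNGScope scope;
  const int n = x.size();
  double dbar = 0.0, s2 = 0.0;
  for (int i = 0; i < n; ++i) dbar += x[i];
  dbar /= n;
  for (int i = 0; i < n; ++i) s2 += (x[i] - dbar) * (x[i] - dbar);
  double sdx = std::sqrt(s2 / std::max(1, n - 1));
  if (!(sdx > 0.0)) sdx = 1e-8; // degenerate (constant) data: handled upstream

  NumericMatrix mu_out(iter, n_chains), sig_out(iter, n_chains),
      alp_out(iter, n_chains);
  NumericVector acc_rate(n_chains);

  // method-of-moments starting point (translation-equivariant): sample
  // skewness -> shape delta, then scale and location from variance and mean
  double m2 = 0.0, m3 = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = x[i] - dbar;
    m2 += d * d;
    m3 += d * d * d;
  }
  m2 /= n;
  m3 /= n;
  double g1 = m3 / std::pow(m2, 1.5);
  if (g1 > 0.9) g1 = 0.9;
  if (g1 < -0.9) g1 = -0.9;
  const double ag = std::pow(std::fabs(g1), 2.0 / 3.0);
  double delta = std::sqrt(M_PI_2 * ag /
                           (ag + std::pow((4.0 - M_PI) / 2.0, 2.0 / 3.0)));
  if (delta > 0.995) delta = 0.995;
  if (g1 < 0) delta = -delta;
  const double alpha0 = delta / std::sqrt(1.0 - delta * delta);
  const double sigma0 =
      std::sqrt(m2 / (1.0 - 2.0 * delta * delta / M_PI));
  const double mu0 = dbar - sigma0 * delta * std::sqrt(2.0 / M_PI);

  for (int c = 0; c < n_chains; ++c) {
    // mildly over-dispersed initial values around the moment estimate
    double th[3];
    th[0] = mu0 + 0.1 * sigma0 * norm_rand();
    th[1] = std::log(sigma0) + 0.1 * norm_rand();
    th[2] = alpha0 + 0.5 * norm_rand();
    double lp = sn_logpost(x, th[0], th[1], th[2], dbar, prior_mu_sd,
                           prior_sigma_beta, prior_alpha_sd);

    // warmup phase 1: per-coordinate random-walk with scale adaptation
    // (finds the typical set); phase 2: joint proposals with covariance
    // estimated from phase-2 states only, global scale adapted throughout
    const int phase1 = warmup * 2 / 5;
    double step[3] = {sdx / std::sqrt((double)n),
                      1.0 / std::sqrt(2.0 * n), 0.25};
    double L[3][3] = {{step[0], 0, 0}, {0, step[1], 0}, {0, 0, step[2]}};
    double lscale = 0.0;
    double m[3] = {0, 0, 0};
    double C[3][3] = {{0}};
    int nadapt = 0, acc = 0;
    const int total = warmup + iter;

    for (int t = 0; t < total; ++t) {
      bool accept = false;
      if (t < phase1) {
        // Metropolis-within-Gibbs, one coordinate per sub-step
        for (int i = 0; i < 3; ++i) {
          double prop[3] = {th[0], th[1], th[2]};
          prop[i] += step[i] * norm_rand();
          const double lpp =
              sn_logpost(x, prop[0], prop[1], prop[2], dbar, prior_mu_sd,
                         prior_sigma_beta, prior_alpha_sd);
          const bool a = std::log(unif_rand()) < lpp - lp;
          if (a) { th[i] = prop[i]; lp = lpp; }
          step[i] *= std::exp(((a ? 1.0 : 0.0) - 0.44) /
                              std::sqrt((double)t + 1.0));
        }
      } else {
        double z[3] = {norm_rand(), norm_rand(), norm_rand()};
        double prop[3];
        const double sc = std::exp(lscale);
        for (int i = 0; i < 3; ++i) {
          double d = 0.0;
          for (int j = 0; j <= i; ++j) d += L[i][j] * z[j];
          prop[i] = th[i] + sc * d;
        }
        const double lpp =
            sn_logpost(x, prop[0], prop[1], prop[2], dbar, prior_mu_sd,
                       prior_sigma_beta, prior_alpha_sd);
        accept = std::log(unif_rand()) < lpp - lp;
        if (accept) {
          for (int i = 0; i < 3; ++i) th[i] = prop[i];
          lp = lpp;
        }
      }

      if (t >= phase1 && t < warmup) {
        // global scale toward 0.3 acceptance, rate decaying in phase-2 time
        lscale += ((accept ? 1.0 : 0.0) - 0.3) /
                  std::sqrt((double)(t - phase1) + 1.0);
        ++nadapt;
        double d0[3];
        for (int i = 0; i < 3; ++i) {
          d0[i] = th[i] - m[i];
          m[i] += d0[i] / nadapt;
        }
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j <= i; ++j)
            C[i][j] += d0[i] * (th[j] - m[j]);
        // refresh Cholesky of 2.38^2/3 * Cov + eps I periodically
        if (nadapt > 100 && t % 50 == 0) {
          double S[3][3];
          const double f = (2.38 * 2.38 / 3.0) / (nadapt - 1);
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              S[i][j] = f * (j <= i ? C[i][j] : C[j][i]);
          for (int i = 0; i < 3; ++i) S[i][i] += 1e-12 + 1e-6 * S[i][i];
          bool ok = true;
          double T[3][3] = {{0}};
          for (int i = 0; i < 3 && ok; ++i) {
            for (int j = 0; j <= i; ++j) {
              double s = S[i][j];
              for (int k = 0; k < j; ++k) s -= T[i][k] * T[j][k];
              if (i == j) {
                if (s <= 0.0) { ok = false; break; }
                T[i][i] = std::sqrt(s);
              } else {
                T[i][j] = s / T[j][j];
              }
            }
          }
          if (ok)
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j) L[i][j] = T[i][j];
        }
      } else if (t >= warmup) {
        if (accept) ++acc;
        const int k = t - warmup;
        mu_out(k, c) = th[0];
        sig_out(k, c) = std::exp(th[1]);
        alp_out(k, c) = th[2];
      }
    }
    acc_rate[c] = (double)acc / iter;
  }

  return List::create(_["mu"] = mu_out, _["sigma"] = sig_out,
                      _["alpha"] = alp_out, _["accept_rate"] = acc_rate,
                      _["dbar"] = dbar);
}
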