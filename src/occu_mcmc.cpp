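#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-species hierarchical occupancy sampler (Metropolis-within-Gibbs).
//
// Model, for species i = 1..S and site j = 1..J:
//   z[i,j]          ~ Bernoulli(psi[i,j]),  logit psi[i,j] = Xocc[j,] %*% alpha[i,]
//   y[i,j] | z[i,j] ~ Binomial(K[j], z[i,j] * p[i,j]), logit p[i,j] = Xdet[j,] %*% beta[i,]
//   alpha[i,k] ~ N(mu_a[k], sd_a[k]^2), beta[i,q] ~ N(mu_b[q], sd_b[q]^2)
//   mu ~ N(0, mu_prior_sd^2), sd ~ Uniform(0, sigma_upper)
//
// Updates: z from its exact Bernoulli full conditional; coefficients by
// adaptive random-walk Metropolis (adaptation frozen after burn-in, so the
// retained draws target the exact posterior); mu by its conjugate normal
// full conditional; sd via the Gamma full conditional of the precision under
// the p(tau) ~ tau^{-3/2} transform of the uniform prior on sd, rejected
// outside (0, sigma_upper).
//
// When S == 1 the community layer is unidentifiable; the hyper layer is
// skipped and coefficients get the fixed vague prior N(0, mu_prior_sd^2).

static inline double lse(double x) {
  // log(1 + exp(x)), stable
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// occupancy-state log-likelihood contribution of eta (logit psi) given z
static inline double ll_occ(double eta, int z) {
  return z ? -lse(-eta) : -lse(eta);
}

// detection log-likelihood of one occupied site (binomial, constant dropped)
static inline double ll_det(double eta, int y, int K) {
  return y * eta - K * lse(eta);
}

// [[Rcpp::export]]
List cpp_occu_chain(IntegerMatrix y, IntegerVector K,
                    NumericMatrix Xocc, NumericMatrix Xdet,
                    int n_burn, int n_iter, int thin,
                    double mu_prior_sd, double sigma_upper,
                    bool store_z) {
  const int S = y.nrow(), J = y.ncol();
  const int P = Xocc.ncol(), Q = Xdet.ncol();
  if (Xocc.nrow() != J || Xdet.nrow() != J)
    stop("design matrices must have one row per site");
  if (thin < 1 || n_iter < thin) stop("invalid iteration/thin settings");
  const bool hier = (S > 1);
  const int n_keep = n_iter / thin;

  // state
  NumericMatrix alpha(S, P), beta(S, Q);
  NumericVector mu_a(P), sd_a(P, 1.0), mu_b(Q), sd_b(Q, 1.0);
  IntegerMatrix z(S, J);
  NumericMatrix eta_occ(S, J), eta_det(S, J);

  for (int i = 0; i < S; ++i) {
    for (int k = 0; k < P; ++k) alpha(i, k) = R::rnorm(0.0, 0.5);
    for (int q = 0; q < Q; ++q) beta(i, q) = R::rnorm(0.0, 0.5);
  }
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < J; ++j) {
      double eo = 0.0, ed = 0.0;
      for (int k = 0; k < P; ++k) eo += Xocc(j, k) * alpha(i, k);
      for (int q = 0; q < Q; ++q) ed += Xdet(j, q) * beta(i, q);
      eta_occ(i, j) = eo; eta_det(i, j) = ed;
      z(i, j) = (y(i, j) > 0) ? 1 : (R::unif_rand() < 0.5 ? 1 : 0);
    }

  // adaptive proposal scales
  NumericMatrix step_a(S, P), step_b(S, Q);
  std::fill(step_a.begin(), step_a.end(), 0.5);
  std::fill(step_b.begin(), step_b.end(), 0.5);
  IntegerMatrix acc_a(S, P), acc_b(S, Q);
  const int adapt_window = 50;

  // output
  NumericMatrix out_alpha(n_keep, S * P), out_beta(n_keep, S * Q);
  NumericMatrix out_mu_a(n_keep, P), out_sd_a(n_keep, P);
  NumericMatrix out_mu_b(n_keep, Q), out_sd_b(n_keep, Q);
  IntegerVector out_z(store_z ? n_keep * S * J : 0);

  int kept = 0;
  const int total = n_burn + n_iter;

  for (int it = 1; it <= total; ++it) {
    // --- occurrence coefficients ---
    for (int i = 0; i < S; ++i) {
      for (int k = 0; k < P; ++k) {
        double cur = alpha(i, k);
        double prop = cur + step_a(i, k) * R::norm_rand();
        double d = prop - cur;
        double ll = 0.0;
        for (int j = 0; j < J; ++j) {
          double e_new = eta_occ(i, j) + d * Xocc(j, k);
          ll += ll_occ(e_new, z(i, j)) - ll_occ(eta_occ(i, j), z(i, j));
        }
        double pm = hier ? mu_a[k] : 0.0;
        double ps = hier ? sd_a[k] : mu_prior_sd;
        ll += R::dnorm(prop, pm, ps, 1) - R::dnorm(cur, pm, ps, 1);
        if (std::log(R::unif_rand()) < ll) {
          alpha(i, k) = prop;
          for (int j = 0; j < J; ++j) eta_occ(i, j) += d * Xocc(j, k);
          acc_a(i, k)++;
        }
      }
    }

    // --- detection coefficients ---
    for (int i = 0; i < S; ++i) {
      for (int q = 0; q < Q; ++q) {
        double cur = beta(i, q);
        double prop = cur + step_b(i, q) * R::norm_rand();
        double d = prop - cur;
        double ll = 0.0;
        for (int j = 0; j < J; ++j) {
          if (!z(i, j)) continue;  // unoccupied sites carry no detection info
          double e_new = eta_det(i, j) + d * Xdet(j, q);
          ll += ll_det(e_new, y(i, j), K[j]) - ll_det(eta_det(i, j), y(i, j), K[j]);
        }
        double pm = hier ? mu_b[q] : 0.0;
        double ps = hier ? sd_b[q] : mu_prior_sd;
        ll += R::dnorm(prop, pm, ps, 1) - R::dnorm(cur, pm, ps, 1);
        if (std::log(R::unif_rand()) < ll) {
          beta(i, q) = prop;
          for (int j = 0; j < J; ++j) eta_det(i, j) += d * Xdet(j, q);
          acc_b(i, q)++;
        }
      }
    }

    // --- latent occupancy (only free where nothing was detected) ---
    for (int i = 0; i < S; ++i)
      for (int j = 0; j < J; ++j) {
        if (y(i, j) > 0) { z(i, j) = 1; continue; }
        // logit Pr(z=1 | y=0) = eta_occ + K * log(1 - p)
        double lo = eta_occ(i, j) - K[j] * lse(eta_det(i, j));
        double pz = 1.0 / (1.0 + std::exp(-lo));
        z(i, j) = (R::unif_rand() < pz) ? 1 : 0;
      }

    // --- community hyper-parameters ---
    if (hier) {
      for (int k = 0; k < P; ++k) {
        double sum = 0.0;
        for (int i = 0; i < S; ++i) sum += alpha(i, k);
        double prec = S / (sd_a[k] * sd_a[k]) + 1.0 / (mu_prior_sd * mu_prior_sd);
        double mean = (sum / (sd_a[k] * sd_a[k])) / prec;
        mu_a[k] = R::rnorm(mean, std::sqrt(1.0 / prec));
        double ss = 0.0;
        for (int i = 0; i < S; ++i) {
          double r = alpha(i, k) - mu_a[k]; ss += r * r;
        }
        double shape = (S - 1) / 2.0;
        if (shape > 0 && ss > 0) {
          for (int att = 0; att < 100; ++att) {
            double tau = R::rgamma(shape, 2.0 / ss);
            double sig = 1.0 / std::sqrt(tau);
            if (sig < sigma_upper) { sd_a[k] = sig; break; }
          }
        }
      }
      for (int q = 0; q < Q; ++q) {
        double sum = 0.0;
        for (int i = 0; i < S; ++i) sum += beta(i, q);
        double prec = S / (sd_b[q] * sd_b[q]) + 1.0 / (mu_prior_sd * mu_prior_sd);
        double mean = (sum / (sd_b[q] * sd_b[q])) / prec;
        mu_b[q] = R::rnorm(mean, std::sqrt(1.0 / prec));
        double ss = 0.0;
        for (int i = 0; i < S; ++i) {
          double r = beta(i, q) - mu_b[q]; ss += r * r;
        }
        double shape = (S - 1) / 2.0;
        if (shape > 0 && ss > 0) {
          for (int att = 0; att < 100; ++att) {
            double tau = R::rgamma(shape, 2.0 / ss);
            double sig = 1.0 / std::sqrt(tau);
            if (sig < sigma_upper) { sd_b[q] = sig; break; }
          }
        }
      }
    }

    // --- proposal adaptation, burn-in only ---
    if (it <= n_burn && it % adapt_window == 0) {
      for (int i = 0; i < S; ++i) {
        for (int k = 0; k < P; ++k) {
          double rate = acc_a(i, k) / (double)adapt_window;
          step_a(i, k) *= (rate > 0.44) ? 1.15 : 0.87;
          if (step_a(i, k) < 1e-3) step_a(i, k) = 1e-3;
          if (step_a(i, k) > 10.0) step_a(i, k) = 10.0;
          acc_a(i, k) = 0;
        }
        for (int q = 0; q < Q; ++q) {
          double rate = acc_b(i, q) / (double)adapt_window;
          step_b(i, q) *= (rate > 0.44) ? 1.15 : 0.87;
          if (step_b(i, q) < 1e-3) step_b(i, q) = 1e-3;
          if (step_b(i, q) > 10.0) step_b(i, q) = 10.0;
          acc_b(i, q) = 0;
        }
      }
    }

    // --- record ---
    if (it > n_burn && (it - n_burn) % thin == 0) {
      for (int i = 0; i < S; ++i)
        for (int k = 0; k < P; ++k) out_alpha(kept, i + S * k) = alpha(i, k);
      for (int i = 0; i < S; ++i)
        for (int q = 0; q < Q; ++q) out_beta(kept, i + S * q) = beta(i, q);
      for (int k = 0; k < P; ++k) { out_mu_a(kept, k) = mu_a[k]; out_sd_a(kept, k) = sd_a[k]; }
      for (int q = 0; q < Q; ++q) { out_mu_b(kept, q) = mu_b[q]; out_sd_b(kept, q) = sd_b[q]; }
      if (store_z) {
        R_xlen_t off = (R_xlen_t)kept * S * J;
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < S; ++i) out_z[off + i + (R_xlen_t)S * j] = z(i, j);
      }
      ++kept;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["alpha"] = out_alpha, _["beta"] = out_beta,
    _["mu_alpha"] = out_mu_a, _["sd_alpha"] = out_sd_a,
    _["mu_beta"] = out_mu_b, _["sd_beta"] = out_sd_b,
    _["z"] = out_z, _["n_keep"] = n_keep);
}
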