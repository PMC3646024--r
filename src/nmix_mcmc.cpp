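#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// One chain of the data-augmented Metropolis-within-Gibbs sampler for the
// binomial-mixture (N-mixture) abundance model.
//
//   N_i ~ Poisson(lambda_i), log lambda_i = x_i' beta       (family = 0)
//   N_i ~ 0 w.p. phi, else Poisson(lambda_i)                (family = 1, ZIP)
//   y_ij | N_i ~ Binomial(N_i, p_ij), logit p_ij = w_ij' alpha [+ eps_ij]
//   eps_ij ~ Normal(0, sigma_p^2)                           (re = true)
//
// Latent N_i move by +/-{1,2} discrete random walk; beta/alpha by
// componentwise adaptive Gaussian random walk (target acceptance 0.44,
// adaptation during burn-in only); eps cellwise random walk; sigma_p by
// random walk on the log scale under a half-Normal prior; the ZIP
// structural-zero indicators and phi by Gibbs.
//
// y uses -1 for missing surveys; missing cells are excluded from every
// likelihood product. Wdet rows are indexed cell = i + S*j (0-based).
// Uses R's RNG, so set.seed() in R makes the chain reproducible.
// [[Rcpp::export(name = ".nmix_mcmc_chain_cpp")]]
List nmix_mcmc_chain_cpp(IntegerMatrix y, NumericMatrix Xab, NumericMatrix Wdet,
                         int family, bool re,
                         int n_iter, int burn, int thin,
                         double prior_sd, double sigma_prior_sd, int n_max,
                         NumericVector alpha_fixed) {
  const int S = y.nrow(), J = y.ncol();
  const int Ka = Xab.ncol(), Kd = Wdet.ncol();
  const int ncell = S * J;
  const double pr_prec = 1.0 / (prior_sd * prior_sd);

  std::vector<int> maxy(S, 0);
  std::vector<char> obs(ncell, 0);
  int nobs = 0;
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < J; ++j) {
      int v = y(i, j);
      if (v == NA_INTEGER || v < 0) continue;
      obs[i + S * j] = 1; ++nobs;
      if (v > maxy[i]) maxy[i] = v;
    }

  // state
  std::vector<double> beta(Ka, 0.0), alpha(Kd, 0.0);
  std::vector<double> loglam(S), eta(ncell, 0.0), eps(ncell, 0.0), p(ncell, 0.0),
      lp(ncell, 0.0), l1mp(ncell, 0.0); // cached log p, log(1-p)
  std::vector<int> N(S);
  // lgamma(k + 1) table for binomial/Poisson ratios
  std::vector<double> lgam(n_max + 3);
  for (int k = 0; k < (int)lgam.size(); ++k) lgam[k] = std::lgamma((double)k + 1.0);
  std::vector<char> w(S, 0); // ZIP structural zero
  double sigma = 0.5, phi = (family == 1) ? 0.2 : 0.0;

  double m0 = 0.0;
  for (int i = 0; i < S; ++i) m0 += maxy[i] + 1.0;
  beta[0] = std::log(m0 / S);
  for (int i = 0; i < S; ++i) {
    N[i] = std::min(maxy[i] + 1, n_max);
    double ll = 0.0;
    for (int k = 0; k < Ka; ++k) ll += Xab(i, k) * beta[k];
    loglam[i] = ll;
  }
  const bool fix_alpha = alpha_fixed.size() > 0;
  if (fix_alpha) {
    for (int k = 0; k < Kd; ++k) alpha[k] = alpha_fixed[k];
  } else {
    alpha[0] = -1.0;
  }
  for (int c = 0; c < ncell; ++c) {
    int i = c % S;
    double e = 0.0;
    for (int k = 0; k < Kd; ++k) e += Wdet(c, k) * alpha[k];
    eta[c] = e;
    p[c] = 1.0 / (1.0 + std::exp(-e));
    lp[c] = std::log(p[c]);
    l1mp[c] = std::log1p(-p[c]);
    (void)i;
  }

  // adaptive scales (log)
  std::vector<double> lsb(Ka, std::log(0.1)), lsa(Kd, std::log(0.1));
  double lse = std::log(0.5), lss = std::log(0.3), lss2 = std::log(0.3);
  std::vector<int> accb(Ka, 0), acca(Kd, 0);
  double acce = 0.0; int accs = 0, accs2 = 0, nbatch = 0;
  const int batch = 50;

  const int nsave = (n_iter - burn) / thin;
  NumericMatrix out_beta(nsave, Ka), out_alpha(nsave, Kd);
  NumericMatrix out_N(nsave, S);
  NumericVector out_sigma(nsave), out_phi(nsave), out_meanp(nsave),
      out_Tobs(nsave), out_Trep(nsave);
  int isave = 0;
  bool hit_nmax = false;

  // log binomial pmf ratio dbinom(y; Nnew, p) - dbinom(y; Nold, p)
  auto detll_ratio = [&](int i, int Nnew, int Nold) {
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      int c = i + S * j;
      if (!obs[c]) continue;
      int yy = y(i, j);
      if (yy > Nnew) return -std::numeric_limits<double>::infinity();
      ll += (lgam[Nnew] - lgam[Nnew - yy]) - (lgam[Nold] - lgam[Nold - yy])
            + (Nnew - Nold) * l1mp[c];
    }
    return ll;
  };

  for (int it = 0; it < n_iter; ++it) {
    // --- latent N ---
    for (int i = 0; i < S; ++i) {
      if (w[i]) continue;
      int step = (int)std::floor(unif_rand() * 4.0); // 0..3
      int d = (step == 0) ? -2 : (step == 1) ? -1 : (step == 2) ? 1 : 2;
      int Np = N[i] + d;
      if (Np < maxy[i] || Np > n_max) continue;
      // Poisson ratio: d*log(lam) - (lgam[Np] - lgam[N])
      double la = d * loglam[i] - (lgam[Np] - lgam[N[i]])
                  + detll_ratio(i, Np, N[i]);
      if (std::log(unif_rand()) < la) N[i] = Np;
      if (N[i] == n_max) hit_nmax = true;
    }

    // --- ZIP indicators and phi ---
    if (family == 1) {
      int sw = 0;
      for (int i = 0; i < S; ++i) {
        if (N[i] > 0) { w[i] = 0; continue; }
        // N_i = 0: all observed y must be 0 (else N could not be 0)
        double lam = std::exp(loglam[i]);
        double p1 = phi, p0 = (1.0 - phi) * std::exp(-lam);
        w[i] = (unif_rand() < p1 / (p1 + p0)) ? 1 : 0;
        if (w[i]) N[i] = 0;
        sw += w[i];
      }
      phi = R::rbeta(1.0 + sw, 1.0 + (S - sw));
    }

    // --- beta ---
    for (int k = 0; k < Ka; ++k) {
      double d = norm_rand() * std::exp(lsb[k]);
      double bnew = beta[k] + d;
      double la = -0.5 * pr_prec * (bnew * bnew - beta[k] * beta[k]);
      bool bad = false;
      for (int i = 0; i < S; ++i) {
        if (family == 1 && w[i]) continue;
        double llnew = loglam[i] + Xab(i, k) * d;
        if (llnew > 30.0) { bad = true; break; }
        la += (-std::exp(llnew) + N[i] * llnew) - (-std::exp(loglam[i]) + N[i] * loglam[i]);
      }
      if (!bad && std::log(unif_rand()) < la) {
        beta[k] = bnew;
        for (int i = 0; i < S; ++i) loglam[i] += Xab(i, k) * d;
        ++accb[k];
      }
    }

    // --- alpha ---
    for (int k = 0; fix_alpha ? false : k < Kd; ++k) {
      double d = norm_rand() * std::exp(lsa[k]);
      double anew = alpha[k] + d;
      double la = -0.5 * pr_prec * (anew * anew - alpha[k] * alpha[k]);
      for (int c = 0; c < ncell; ++c) {
        if (!obs[c]) continue;
        int i = c % S;
        if (N[i] == 0) continue; // y = 0 and N = 0: cell contributes nothing
        int yy = y(i, c / S);
        double p1 = 1.0 / (1.0 + std::exp(-(eta[c] + eps[c] + Wdet(c, k) * d)));
        // binomial coefficient cancels: N fixed
        la += yy * (std::log(p1) - lp[c]) + (N[i] - yy) * (std::log1p(-p1) - l1mp[c]);
      }
      if (std::log(unif_rand()) < la) {
        alpha[k] = anew;
        for (int c = 0; c < ncell; ++c) {
          eta[c] += Wdet(c, k) * d;
          if (obs[c]) {
            p[c] = 1.0 / (1.0 + std::exp(-(eta[c] + eps[c])));
            lp[c] = std::log(p[c]);
            l1mp[c] = std::log1p(-p[c]);
          }
        }
        ++acca[k];
      }
    }

    // --- detection random effects ---
    if (re) {
      double se = std::exp(lse);
      double s2 = sigma * sigma;
      int acc_local = 0;
      for (int c = 0; c < ncell; ++c) {
        if (!obs[c]) continue;
        int i = c % S;
        if (N[i] == 0) {
          // likelihood is flat (y = 0, N = 0): conditional = prior, exact Gibbs
          eps[c] = norm_rand() * sigma;
          p[c] = 1.0 / (1.0 + std::exp(-(eta[c] + eps[c])));
          lp[c] = std::log(p[c]);
          l1mp[c] = std::log1p(-p[c]);
          ++acc_local;
          continue;
        }
        int yy = y(i, c / S);
        double enew = eps[c] + norm_rand() * se;
        double p1 = 1.0 / (1.0 + std::exp(-(eta[c] + enew)));
        double llp1 = std::log(p1), ll1mp1 = std::log1p(-p1);
        double la = yy * (llp1 - lp[c]) + (N[i] - yy) * (ll1mp1 - l1mp[c])
                  - 0.5 * (enew * enew - eps[c] * eps[c]) / s2;
        if (std::log(unif_rand()) < la) {
          eps[c] = enew; p[c] = p1; lp[c] = llp1; l1mp[c] = ll1mp1;
          ++acc_local;
        }
      }
      acce += (double)acc_local / (nobs > 0 ? nobs : 1); // mean per-cell rate

      // --- sigma_p, log-scale RW, half-Normal(0, sigma_prior_sd) prior ---
      double lsnew = std::log(sigma) + norm_rand() * std::exp(lss);
      double snew = std::exp(lsnew);
      double la = 0.0;
      double d0 = -0.5 / (sigma * sigma), d1 = -0.5 / (snew * snew);
      double sse = 0.0;
      for (int c = 0; c < ncell; ++c) { if (obs[c]) sse += eps[c] * eps[c]; }
      la += (d1 - d0) * sse + nobs * (std::log(sigma) - std::log(snew));
      la += -0.5 * (snew * snew - sigma * sigma) / (sigma_prior_sd * sigma_prior_sd);
      la += lsnew - std::log(sigma); // Jacobian
      if (std::log(unif_rand()) < la) { sigma = snew; ++accs; }

      // --- sigma_p again, non-centered (eps rescaled with sigma): the
      // interweaved move that breaks the eps/sigma funnel ---
      double ls2 = std::log(sigma) + norm_rand() * std::exp(lss2);
      double s2new = std::exp(ls2);
      double ratio = s2new / sigma;
      double la2 = -0.5 * (s2new * s2new - sigma * sigma) /
                   (sigma_prior_sd * sigma_prior_sd) + (ls2 - std::log(sigma));
      for (int c = 0; c < ncell; ++c) {
        if (!obs[c]) continue;
        int i = c % S;
        if (N[i] == 0) continue;
        int yy = y(i, c / S);
        double p1 = 1.0 / (1.0 + std::exp(-(eta[c] + eps[c] * ratio)));
        la2 += yy * (std::log(p1) - lp[c]) + (N[i] - yy) * (std::log1p(-p1) - l1mp[c]);
      }
      if (std::log(unif_rand()) < la2) {
        sigma = s2new;
        for (int c = 0; c < ncell; ++c) {
          if (!obs[c]) continue;
          eps[c] *= ratio;
          p[c] = 1.0 / (1.0 + std::exp(-(eta[c] + eps[c])));
          lp[c] = std::log(p[c]);
          l1mp[c] = std::log1p(-p[c]);
        }
        ++accs2;
      }
    }

    // --- adaptation ---
    if (it < burn && (it + 1) % batch == 0) {
      ++nbatch;
      double gain = std::min(0.05, 1.0 / std::sqrt((double)nbatch));
      for (int k = 0; k < Ka; ++k) {
        lsb[k] += (accb[k] > 0.44 * batch ? gain : -gain); accb[k] = 0;
      }
      for (int k = 0; k < Kd; ++k) {
        lsa[k] += (acca[k] > 0.44 * batch ? gain : -gain); acca[k] = 0;
      }
      if (re) {
        lse += (acce > 0.44 * batch ? gain : -gain); acce = 0;
        lss += (accs > 0.44 * batch ? gain : -gain); accs = 0;
        lss2 += (accs2 > 0.44 * batch ? gain : -gain); accs2 = 0;
      }
    }

    // --- save ---
    if (it >= burn && (it - burn) % thin == 0 && isave < nsave) {
      for (int k = 0; k < Ka; ++k) out_beta(isave, k) = beta[k];
      for (int k = 0; k < Kd; ++k) out_alpha(isave, k) = alpha[k];
      for (int i = 0; i < S; ++i) out_N(isave, i) = N[i];
      out_sigma[isave] = sigma;
      out_phi[isave] = phi;
      double Tobs = 0.0, Trep = 0.0, psum = 0.0;
      for (int c = 0; c < ncell; ++c) {
        if (!obs[c]) continue;
        int i = c % S, j = c / S;
        double pc = p[c];
        psum += pc;
        double mu = N[i] * pc;
        double r = y(i, j) - mu;
        Tobs += r * r / (mu + 0.5);
        double yr = (N[i] > 0) ? R::rbinom((double)N[i], pc) : 0.0;
        double rr = yr - mu;
        Trep += rr * rr / (mu + 0.5);
      }
      out_meanp[isave] = psum / nobs;
      out_Tobs[isave] = Tobs;
      out_Trep[isave] = Trep;
      ++isave;
    }
  }

  return List::create(
      _["beta"] = out_beta, _["alpha"] = out_alpha, _["N"] = out_N,
      _["sigma"] = out_sigma, _["phi"] = out_phi, _["mean_p"] = out_meanp,
      _["T_obs"] = out_Tobs, _["T_rep"] = out_Trep,
      _["hit_nmax"] = hit_nmax);
}
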