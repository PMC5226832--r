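#include <Rcpp.h>
using namespace Rcpp;

// Model variants share a two-rate Poisson likelihood switched at per-day
// (or pooled) sleep/wake bin indices.  Variant codes:
//   0 pooled-pooled, 1 independent-pooled, 2 independent-independent,
//   3 independent-hyper, 4 hyper-hyper.
// Day likelihoods are O(1) via per-day prefix sums of the count matrix:
// with S = sleep bins [ceil(ts), ceil(ta)-1] the Poisson log likelihood is
//   Ks log(ls) - Ns ls + Ka log(la) - Na la - sum(lgamma(k+1)).

static inline double dexp_log(double x, double rate) {
  if (x < 0.0) return R_NegInf;
  return std::log(rate) - rate * x;
}

static inline double dgamma_log(double x, double shape, double rate) {
  if (x <= 0.0) return R_NegInf;
  return shape * std::log(rate) - R::lgammafn(shape) +
         (shape - 1.0) * std::log(x) - rate * x;
}

// normal parameterized by precision tau
static inline double dnorm_prec_log(double x, double mu, double tau) {
  return 0.5 * std::log(tau) - 0.5 * std::log(2.0 * M_PI) -
         0.5 * tau * (x - mu) * (x - mu);
}

static inline double loglik_day(const NumericMatrix& P,
                                const NumericVector& Ktot,
                                const NumericVector& Cn,
                                int i, int n,
                                double ts, double ta,
                                double ls, double la) {
  int lo = (int)std::ceil(ts);
  if (lo < 0) lo = 0;
  int hi = (int)std::ceil(ta) - 1;
  if (hi > n - 1) hi = n - 1;
  double Ks = 0.0;
  int Ns = 0;
  if (hi >= lo) {
    Ks = P(i, hi + 1) - P(i, lo);
    Ns = hi - lo + 1;
  }
  double Ka = Ktot[i] - Ks;
  int Na = n - Ns;
  return Ks * std::log(ls) - (double)Ns * ls +
         Ka * std::log(la) - (double)Na * la - Cn[i];
}

struct Consts {
  double b_sleep;   // exponential rate for lambda_sleep prior
  double a_awake;   // gamma shape for lambda_awake prior
  double r_awake;   // gamma rate for lambda_awake prior
  double r_hyper;   // exponential rate for all hyperparameter priors
  double mu_ts;     // prior center of t_sleep (bins), hyper-hyper only
  double mu_ta;     // prior center of t_awake (bins), hyper-hyper only
};

static Consts read_consts(const List& consts) {
  Consts c;
  c.b_sleep = as<double>(consts["sleep_rate_prior_rate"]);
  c.a_awake = as<double>(consts["awake_gamma_shape"]);
  c.r_awake = as<double>(consts["awake_gamma_rate"]);
  c.r_hyper = as<double>(consts["hyper_exp_rate"]);
  c.mu_ts = as<double>(consts["tsleep_center_bin"]);
  c.mu_ta = as<double>(consts["tawake_center_bin"]);
  return c;
}

// Full log prior for the current state; R_NegInf outside the support.
// Switchpoints live on [0, n]; discrete variants carry the uniform
// -log(n+1) mass per switchpoint, the hyper-hyper variant a Normal
// (precision tau_t) truncated to [0, n] (normalizer omitted; mass
// outside is negligible at the scales used).
static double log_prior(int variant, int n, int m, const Consts& c,
                        double ls, const NumericVector& la,
                        const NumericVector& ts, const NumericVector& ta,
                        double al, double bl,
                        double at, double bt, double tau) {
  if (ls <= 0.0) return R_NegInf;
  for (int j = 0; j < la.size(); ++j)
    if (la[j] <= 0.0) return R_NegInf;
  for (int j = 0; j < ts.size(); ++j)
    if (ts[j] < 0.0 || ts[j] > n || ta[j] < 0.0 || ta[j] > n)
      return R_NegInf;

  double lp = dexp_log(ls, c.b_sleep);

  if (variant <= 2) {  // lambda_awake ~ Gamma(a_awake, r_awake)
    for (int j = 0; j < la.size(); ++j)
      lp += dgamma_log(la[j], c.a_awake, c.r_awake);
  } else {             // lambda_awake_i ~ Gamma(alpha_lambda, beta_lambda)
    if (al <= 0.0 || bl <= 0.0) return R_NegInf;
    lp += dexp_log(al, c.r_hyper) + dexp_log(bl, c.r_hyper);
    for (int j = 0; j < la.size(); ++j)
      lp += dgamma_log(la[j], al, bl);
  }

  if (variant <= 3) {  // discrete uniform switchpoints on {0..n}
    lp += -(double)(ts.size() + ta.size()) * std::log((double)(n + 1));
  } else {             // hyper-hyper: Normal(mu, precision tau_t)
    if (at <= 0.0 || bt <= 0.0 || tau <= 0.0) return R_NegInf;
    lp += dexp_log(at, c.r_hyper) + dexp_log(bt, c.r_hyper) +
          dgamma_log(tau, at, bt);
    for (int j = 0; j < ts.size(); ++j) {
      lp += dnorm_prec_log(ts[j], c.mu_ts, tau);
      lp += dnorm_prec_log(ta[j], c.mu_ta, tau);
    }
  }
  return lp;
}

// [[Rcpp::export]]
double cpp_log_joint(IntegerMatrix counts, int variant, List consts,
                     double lambda_sleep, NumericVector lambda_awake,
                     NumericVector t_sleep, NumericVector t_awake,
                     double alpha_lambda, double beta_lambda,
                     double alpha_t, double beta_t, double tau_t) {
  int m = counts.nrow(), n = counts.ncol();
  Consts c = read_consts(consts);
  double lp = log_prior(variant, n, m, c, lambda_sleep, lambda_awake,
                        t_sleep, t_awake, alpha_lambda, beta_lambda,
                        alpha_t, beta_t, tau_t);
  if (!R_FINITE(lp)) return R_NegInf;

  NumericMatrix P(m, n + 1);
  NumericVector Ktot(m), Cn(m);
  for (int i = 0; i < m; ++i) {
    double acc = 0.0, cl = 0.0;
    P(i, 0) = 0.0;
    for (int t = 0; t < n; ++t) {
      acc += counts(i, t);
      P(i, t + 1) = acc;
      cl += R::lgammafn(counts(i, t) + 1.0);
    }
    Ktot[i] = acc;
    Cn[i] = cl;
  }
  for (int i = 0; i < m; ++i) {
    double tsi = t_sleep.size() > 1 ? t_sleep[i] : t_sleep[0];
    double tai = t_awake.size() > 1 ? t_awake[i] : t_awake[0];
    double lai = lambda_awake.size() > 1 ? lambda_awake[i] : lambda_awake[0];
    lp += loglik_day(P, Ktot, Cn, i, n, tsi, tai, lambda_sleep, lai);
  }
  return lp;
}

// Poisson log likelihood per posterior sample; columns of the time/rate
// matrices broadcast across days when of width 1.
// [[Rcpp::export]]
NumericVector cpp_loglik_trace(IntegerMatrix counts,
                               NumericVector lambda_sleep,
                               NumericMatrix lambda_awake,
                               NumericMatrix t_sleep,
                               NumericMatrix t_awake) {
  int m = counts.nrow(), n = counts.ncol();
  int S = lambda_sleep.size();
  NumericMatrix P(m, n + 1);
  NumericVector Ktot(m), Cn(m);
  for (int i = 0; i < m; ++i) {
    double acc = 0.0, cl = 0.0;
    for (int t = 0; t < n; ++t) {
      acc += counts(i, t);
      P(i, t + 1) = acc;
      cl += R::lgammafn(counts(i, t) + 1.0);
    }
    Ktot[i] = acc;
    Cn[i] = cl;
  }
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    double ll = 0.0;
    for (int i = 0; i < m; ++i) {
      double tsi = t_sleep.ncol() > 1 ? t_sleep(s, i) : t_sleep(s, 0);
      double tai = t_awake.ncol() > 1 ? t_awake(s, i) : t_awake(s, 0);
      double lai = lambda_awake.ncol() > 1 ? lambda_awake(s, i)
                                           : lambda_awake(s, 0);
      ll += loglik_day(P, Ktot, Cn, i, n, tsi, tai, lambda_sleep[s], lai);
    }
    out[s] = ll;
  }
  return out;
}

static inline double propose_bin(double cur, int n, bool* in_support) {
  double prop;
  if (unif_rand() < 0.05) {
    prop = std::floor(unif_rand() * (double)(n + 1));  // uniform restart
  } else {
    int step = 1 + (int)std::floor(unif_rand() * 4.0);
    if (unif_rand() < 0.5) step = -step;
    prop = cur + step;
  }
  *in_support = (prop >= 0.0 && prop <= (double)n);
  return prop;
}

static inline double propose_time_cont(double cur, double sd, int n,
                                       bool* in_support) {
  double prop;
  if (unif_rand() < 0.05) {
    prop = unif_rand() * (double)n;
  } else {
    prop = cur + sd * norm_rand();
  }
  *in_support = (prop >= 0.0 && prop <= (double)n);
  return prop;
}

// Metropolis-within-Gibbs over the model state.  Discrete switchpoints move
// by +/-1..4 integer steps with a 5% uniform restart (irreducible over
// {0..n}); positive parameters use a log-scale Gaussian random walk with
// step sizes adapted toward 0.44 acceptance during burn-in; hyper-hyper
// times use a reflectionless Gaussian walk with the same 5% restart.
// [[Rcpp::export]]
List cpp_sample(IntegerMatrix counts, int variant, List consts,
                int n_samples, int burn_in, List init, List fixed) {
  int m = counts.nrow(), n = counts.ncol();
  Consts c = read_consts(consts);

  NumericMatrix P(m, n + 1);
  NumericVector Ktot(m), Cn(m);
  for (int i = 0; i < m; ++i) {
    double acc = 0.0, cl = 0.0;
    for (int t = 0; t < n; ++t) {
      acc += counts(i, t);
      P(i, t + 1) = acc;
      cl += R::lgammafn(counts(i, t) + 1.0);
    }
    Ktot[i] = acc;
    Cn[i] = cl;
  }

  bool day_times = variant >= 1;
  bool day_rates = variant >= 2;
  bool hyper_rates = variant >= 3;
  bool hyper_times = variant == 4;
  int mt = day_times ? m : 1;   // number of switchpoint pairs
  int mr = day_rates ? m : 1;   // number of awake rates

  double ls = as<double>(init["lambda_sleep"]);
  NumericVector la = clone(as<NumericVector>(init["lambda_awake"]));
  NumericVector ts = clone(as<NumericVector>(init["t_sleep"]));
  NumericVector ta = clone(as<NumericVector>(init["t_awake"]));
  double al = as<double>(init["alpha_lambda"]);
  double bl = as<double>(init["beta_lambda"]);
  double at = as<double>(init["alpha_t"]);
  double bt = as<double>(init["beta_t"]);
  double tau = as<double>(init["tau_t"]);

  bool fix_times = fixed.containsElementNamed("t_sleep");
  if (fix_times) {
    NumericVector fts = as<NumericVector>(fixed["t_sleep"]);
    NumericVector fta = as<NumericVector>(fixed["t_awake"]);
    for (int j = 0; j < mt; ++j) {
      ts[j] = fts.size() > 1 ? fts[j] : fts[0];
      ta[j] = fta.size() > 1 ? fta[j] : fta[0];
    }
  }

  // current per-day log likelihood
  NumericVector ll(m);
  for (int i = 0; i < m; ++i) {
    double tsi = ts[mt > 1 ? i : 0], tai = ta[mt > 1 ? i : 0];
    double lai = la[mr > 1 ? i : 0];
    ll[i] = loglik_day(P, Ktot, Cn, i, n, tsi, tai, ls, lai);
  }

  // adaptive step sizes (log scale for positive params)
  double s_ls = 0.8, s_la = 0.3, s_t = 2.0, s_hyp = 0.5;
  int acc_ls = 0, try_ls = 0, acc_la = 0, try_la = 0;
  int acc_t = 0, try_t = 0, acc_hyp = 0, try_hyp = 0;

  int n_par = 1 + mr + 2 * mt + (hyper_rates ? 2 : 0) + (hyper_times ? 3 : 0);
  NumericMatrix out(n_samples, n_par);
  NumericVector out_logp(n_samples);

  int total_iter = burn_in + n_samples;
  for (int it = 0; it < total_iter; ++it) {
    // lambda_sleep: log-scale random walk, likelihood over all days
    {
      double prop = ls * std::exp(s_ls * norm_rand());
      double d = dexp_log(prop, c.b_sleep) - dexp_log(ls, c.b_sleep) +
                 std::log(prop) - std::log(ls);
      NumericVector nll(m);
      for (int i = 0; i < m; ++i) {
        nll[i] = loglik_day(P, Ktot, Cn, i, n, ts[mt > 1 ? i : 0],
                            ta[mt > 1 ? i : 0], prop, la[mr > 1 ? i : 0]);
        d += nll[i] - ll[i];
      }
      ++try_ls;
      if (std::log(unif_rand()) < d) {
        ls = prop;
        ll = nll;
        ++acc_ls;
      }
    }

    // awake rates
    for (int j = 0; j < mr; ++j) {
      double prop = la[j] * std::exp(s_la * norm_rand());
      double dprior =
          hyper_rates
              ? dgamma_log(prop, al, bl) - dgamma_log(la[j], al, bl)
              : dgamma_log(prop, c.a_awake, c.r_awake) -
                    dgamma_log(la[j], c.a_awake, c.r_awake);
      double d = dprior + std::log(prop) - std::log(la[j]);
      if (mr > 1) {
        double nll = loglik_day(P, Ktot, Cn, j, n, ts[mt > 1 ? j : 0],
                                ta[mt > 1 ? j : 0], ls, prop);
        d += nll - ll[j];
        ++try_la;
        if (std::log(unif_rand()) < d) {
          la[j] = prop;
          ll[j] = nll;
          ++acc_la;
        }
      } else {
        NumericVector nll(m);
        for (int i = 0; i < m; ++i) {
          nll[i] = loglik_day(P, Ktot, Cn, i, n, ts[mt > 1 ? i : 0],
                              ta[mt > 1 ? i : 0], ls, prop);
          d += nll[i] - ll[i];
        }
        ++try_la;
        if (std::log(unif_rand()) < d) {
          la[j] = prop;
          ll = nll;
          ++acc_la;
        }
      }
    }

    // switchpoints
    if (!fix_times) {
      for (int j = 0; j < mt; ++j) {
        for (int which = 0; which < 2; ++which) {
          NumericVector& tv = which == 0 ? ts : ta;
          double cur = tv[j];
          bool ok;
          double prop = hyper_times ? propose_time_cont(cur, s_t, n, &ok)
                                    : propose_bin(cur, n, &ok);
          ++try_t;
          if (!ok) continue;
          double dprior = 0.0;
          if (hyper_times) {
            double mu = which == 0 ? c.mu_ts : c.mu_ta;
            dprior = dnorm_prec_log(prop, mu, tau) -
                     dnorm_prec_log(cur, mu, tau);
          }
          if (mt > 1) {
            double tsi = which == 0 ? prop : ts[j];
            double tai = which == 0 ? ta[j] : prop;
            double nll =
                loglik_day(P, Ktot, Cn, j, n, tsi, tai, ls, la[mr > 1 ? j : 0]);
            if (std::log(unif_rand()) < dprior + nll - ll[j]) {
              tv[j] = prop;
              ll[j] = nll;
              ++acc_t;
            }
          } else {
            double d = dprior;
            NumericVector nll(m);
            for (int i = 0; i < m; ++i) {
              double tsi = which == 0 ? prop : ts[0];
              double tai = which == 0 ? ta[0] : prop;
              nll[i] = loglik_day(P, Ktot, Cn, i, n, tsi, tai, ls,
                                  la[mr > 1 ? i : 0]);
              d += nll[i] - ll[i];
            }
            if (std::log(unif_rand()) < d) {
              tv[j] = prop;
              ll = nll;
              ++acc_t;
            }
          }
        }
      }
    }

    // rate hyperparameters
    if (hyper_rates) {
      for (int which = 0; which < 2; ++which) {
        double cur = which == 0 ? al : bl;
        double prop = cur * std::exp(s_hyp * norm_rand());
        double na = which == 0 ? prop : al;
        double nb = which == 0 ? bl : prop;
        double d = dexp_log(prop, c.r_hyper) - dexp_log(cur, c.r_hyper) +
                   std::log(prop) - std::log(cur);
        for (int j = 0; j < mr; ++j)
          d += dgamma_log(la[j], na, nb) - dgamma_log(la[j], al, bl);
        ++try_hyp;
        if (std::log(unif_rand()) < d) {
          al = na;
          bl = nb;
          ++acc_hyp;
        }
      }
    }

    // time hyperparameters
    if (hyper_times) {
      {
        double prop = tau * std::exp(s_hyp * norm_rand());
        double d = dgamma_log(prop, at, bt) - dgamma_log(tau, at, bt) +
                   std::log(prop) - std::log(tau);
        for (int j = 0; j < mt; ++j) {
          d += dnorm_prec_log(ts[j], c.mu_ts, prop) -
               dnorm_prec_log(ts[j], c.mu_ts, tau);
          d += dnorm_prec_log(ta[j], c.mu_ta, prop) -
               dnorm_prec_log(ta[j], c.mu_ta, tau);
        }
        ++try_hyp;
        if (std::log(unif_rand()) < d) {
          tau = prop;
          ++acc_hyp;
        }
      }
      for (int which = 0; which < 2; ++which) {
        double cur = which == 0 ? at : bt;
        double prop = cur * std::exp(s_hyp * norm_rand());
        double na = which == 0 ? prop : at;
        double nb = which == 0 ? bt : prop;
        double d = dexp_log(prop, c.r_hyper) - dexp_log(cur, c.r_hyper) +
                   std::log(prop) - std::log(cur) +
                   dgamma_log(tau, na, nb) - dgamma_log(tau, at, bt);
        ++try_hyp;
        if (std::log(unif_rand()) < d) {
          at = na;
          bt = nb;
          ++acc_hyp;
        }
      }
    }

    // burn-in step adaptation toward 0.44 acceptance
    if (it < burn_in && (it + 1) % 50 == 0) {
      if (try_ls > 0) s_ls *= std::exp((double)acc_ls / try_ls - 0.44);
      if (try_la > 0) s_la *= std::exp((double)acc_la / try_la - 0.44);
      if (hyper_times && try_t > 0)
        s_t *= std::exp((double)acc_t / try_t - 0.44);
      if (try_hyp > 0) s_hyp *= std::exp((double)acc_hyp / try_hyp - 0.44);
      s_ls = std::min(std::max(s_ls, 1e-3), 10.0);
      s_la = std::min(std::max(s_la, 1e-3), 10.0);
      s_t = std::min(std::max(s_t, 0.05), (double)n);
      s_hyp = std::min(std::max(s_hyp, 1e-3), 10.0);
      acc_ls = try_ls = acc_la = try_la = 0;
      acc_t = try_t = acc_hyp = try_hyp = 0;
    }

    if (it >= burn_in) {
      int s = it - burn_in;
      int col = 0;
      out(s, col++) = ls;
      for (int j = 0; j < mr; ++j) out(s, col++) = la[j];
      for (int j = 0; j < mt; ++j) out(s, col++) = ts[j];
      for (int j = 0; j < mt; ++j) out(s, col++) = ta[j];
      if (hyper_rates) {
        out(s, col++) = al;
        out(s, col++) = bl;
      }
      if (hyper_times) {
        out(s, col++) = at;
        out(s, col++) = bt;
        out(s, col++) = tau;
      }
      double lp = log_prior(variant, n, m, c, ls, la, ts, ta, al, bl, at, bt,
                            tau);
      for (int i = 0; i < m; ++i) lp += ll[i];
      out_logp[s] = lp;
    }
  }

  return List::create(_["samples"] = out, _["logp"] = out_logp,
                      _["steps"] = NumericVector::create(s_ls, s_la, s_t,
                                                         s_hyp));
}
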