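// Single-chain MCMC for the two-gear occupancy models.
//
// Latent states (site occupancy z, or site abundance N for the
// Royle-Nichols family) are updated by single-site Gibbs / discrete
// Metropolis; regression coefficients by adaptive Gaussian random-walk
// Metropolis under a Student-t prior on the link scale; Kuo-Mallick
// inclusion indicators by Gibbs on their two-point conditional (an excluded
// coefficient is refreshed from its prior); random-effect SDs by Metropolis
// under a Uniform(0, upper) prior. Uses R's RNG so set.seed() on the R side
// makes chains reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double log1p_exp(double x) {
  // log(1 + e^x), stable for both tails
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double lbern_logit(int y, double lp) {
  // log Bernoulli(y | inv_logit(lp))
  return y * lp - log1p_exp(lp);
}

static inline double lbinom_logit(int y, int k, double lp) {
  // log Binomial(y | k, inv_logit(lp)), binomial coefficient dropped
  return -(double)y * log1p_exp(-lp) - (double)(k - y) * log1p_exp(lp);
}

static inline double rn_lbinom(int y, int k, double log1mr, int N) {
  // log Binomial(y | k, 1 - (1-r)^N) with log(1-r) supplied; coef dropped
  if (N == 0) return (y == 0) ? 0.0 : R_NegInf;
  double logq = N * log1mr;                  // log(1 - p)
  if (y == 0) return k * logq;
  double em = -std::expm1(logq);             // p
  if (em <= 0.0) return R_NegInf;
  double logp = std::log(em);
  return y * logp + (k - y) * logq;
}

struct TPrior {
  double sigma, nu;
  double logd(double x) const {
    double u = x / sigma;
    return -0.5 * (nu + 1.0) * std::log1p(u * u / nu);
  }
  double draw() const { return sigma * R::rt(nu); }
};

struct Adapt {
  // Robbins-Monro tuning of log proposal SDs toward 0.44 acceptance
  std::vector<double> ls;
  std::vector<int> n;
  bool frozen;
  Adapt() : frozen(false) {}
  void init(int m, double s0) {
    ls.assign(m, std::log(s0));
    n.assign(m, 0);
  }
  double sd(int j) const { return std::exp(ls[j]); }
  void update(int j, bool acc) {
    if (frozen) return;
    n[j]++;
    double delta = std::min(0.25, 1.0 / std::sqrt((double)n[j]));
    ls[j] += acc ? delta * 0.56 : -delta * 0.44;
    if (ls[j] < -8.0) ls[j] = -8.0;
    if (ls[j] > 4.0) ls[j] = 4.0;
  }
};

class SubModel {
  // one linear predictor block: intercept + X * (w .* b)
public:
  double b0;
  std::vector<double> b;
  std::vector<int> w;
  const NumericMatrix X;
  std::vector<double> lp;   // cached linear predictor (no random effect)
  Adapt adapt;              // slot 0: intercept, slots 1..P: coefficients

  SubModel(const NumericMatrix& X_) : X(X_) {
    int S = X.nrow(), P = X.ncol();
    b0 = 0.0;
    b.assign(P, 0.0);
    w.assign(P, 1);
    lp.assign(S, 0.0);
    adapt.init(P + 1, 0.3);
  }
  int P() const { return (int)b.size(); }
  int S() const { return (int)lp.size(); }
  void refresh_lp() {
    for (int i = 0; i < S(); i++) {
      double s = b0;
      for (int m = 0; m < P(); m++)
        if (w[m]) s += b[m] * X(i, m);
      lp[i] = s;
    }
  }
};

class Sampler {
public:
  int family;               // 0 basic, 1 Royle-Nichols
  IntegerVector y1, y2;
  int k2, S, N_max;
  bool re;                  // site random effect present
  SubModel occ, chev, cam;
  std::vector<int> z;       // basic: occupancy; RN: abundance
  std::vector<double> eps;
  double sigma_eps;
  TPrior tprior;
  double sd_upper, logit_incl;
  Adapt adapt_eps, adapt_sig;
  std::vector<double> scratch;
  double f_occ, f_chev, f_cam;   // cached block log-likelihoods

  Sampler(int family_, IntegerVector y1_, IntegerVector y2_, int k2_,
          const NumericMatrix& Xocc, const NumericMatrix& Xchev,
          const NumericMatrix& Xcam, bool re_, double t_sigma, double t_nu,
          double sd_upper_, double incl_prior, int N_max_)
    : family(family_), y1(y1_), y2(y2_), k2(k2_), S(y1_.size()),
      N_max(N_max_), re(re_), occ(Xocc), chev(Xchev), cam(Xcam) {
    tprior.sigma = t_sigma;
    tprior.nu = t_nu;
    sd_upper = sd_upper_;
    logit_incl = std::log(incl_prior) - std::log1p(-incl_prior);
    z.assign(S, 0);
    for (int i = 0; i < S; i++) {
      if (family == 0) {
        z[i] = (y1[i] > 0 || y2[i] > 0) ? 1 : 0;
      } else {
        int m = std::max((int)y1[i], (int)y2[i]) + 1;
        z[i] = std::min(m, N_max);
      }
    }
    eps.assign(S, 0.0);
    sigma_eps = 1.0;
    adapt_eps.init(1, 0.5);
    adapt_sig.init(1, 0.5);
    scratch.assign(S, 0.0);
    occ.refresh_lp(); chev.refresh_lp(); cam.refresh_lp();
    refresh_liks();
  }

  // ---- block likelihoods given the latent state -------------------------
  double occ_lik(const std::vector<double>& lp) const {
    double s = 0.0;
    if (family == 0) {
      for (int i = 0; i < S; i++) s += lbern_logit(z[i], lp[i]);
    } else {
      for (int i = 0; i < S; i++) {
        double ll = lp[i] + (re ? eps[i] : 0.0);
        s += z[i] * ll - std::exp(ll);
      }
    }
    return s;
  }
  double chev_lik(const std::vector<double>& lp) const {
    double s = 0.0;
    if (family == 0) {
      for (int i = 0; i < S; i++)
        if (z[i]) s += lbern_logit(y1[i], lp[i]);
    } else {
      for (int i = 0; i < S; i++)
        s += rn_lbinom(y1[i], 1, -log1p_exp(lp[i]), z[i]);
    }
    return s;
  }
  double cam_lik(const std::vector<double>& lp) const {
    double s = 0.0;
    if (family == 0) {
      for (int i = 0; i < S; i++)
        if (z[i]) s += lbinom_logit(y2[i], k2, lp[i] + (re ? eps[i] : 0.0));
    } else {
      for (int i = 0; i < S; i++)
        s += rn_lbinom(y2[i], k2, -log1p_exp(lp[i]), z[i]);
    }
    return s;
  }
  void refresh_liks() {
    f_occ = occ_lik(occ.lp);
    f_chev = chev_lik(chev.lp);
    f_cam = cam_lik(cam.lp);
  }

  // ---- latent state updates --------------------------------------------
  void update_z_basic() {
    for (int i = 0; i < S; i++) {
      if (y1[i] > 0 || y2[i] > 0) { z[i] = 1; continue; }
      // log odds of occupancy given an all-zero history
      double logq = -log1p_exp(chev.lp[i]) -
        (double)k2 * log1p_exp(cam.lp[i] + (re ? eps[i] : 0.0));
      double lo = occ.lp[i] + logq;
      z[i] = (R::runif(0.0, 1.0) < 1.0 / (1.0 + std::exp(-lo))) ? 1 : 0;
    }
  }
  double site_lik_N(int i, int n, double log1mr1, double log1mr2) const {
    double ll = occ.lp[i] + (re ? eps[i] : 0.0);
    return n * ll - std::lgamma(n + 1.0) +
      rn_lbinom(y1[i], 1, log1mr1, n) + rn_lbinom(y2[i], k2, log1mr2, n);
  }
  void update_N() {
    for (int i = 0; i < S; i++) {
      int nmin = (y1[i] > 0 || y2[i] > 0) ? 1 : 0;
      double log1mr1 = -log1p_exp(chev.lp[i]);
      double log1mr2 = -log1p_exp(cam.lp[i]);
      int n = z[i], np;
      if (R::runif(0.0, 1.0) < 0.2) {
        // independence proposal from the Poisson prior: the prior and the
        // proposal cancel, leaving the detection-likelihood ratio
        double lam = std::exp(occ.lp[i] + (re ? eps[i] : 0.0));
        np = (int)R::rpois(lam);
        if (np < nmin || np > N_max) continue;
        double lr = rn_lbinom(y1[i], 1, log1mr1, np) +
          rn_lbinom(y2[i], k2, log1mr2, np) -
          rn_lbinom(y1[i], 1, log1mr1, n) -
          rn_lbinom(y2[i], k2, log1mr2, n);
        if (std::log(R::runif(0.0, 1.0)) < lr) z[i] = np;
      } else {
        np = n + (R::runif(0.0, 1.0) < 0.5 ? -1 : 1);
        if (np < nmin || np > N_max) continue;
        double lr = site_lik_N(i, np, log1mr1, log1mr2) -
          site_lik_N(i, n, log1mr1, log1mr2);
        if (std::log(R::runif(0.0, 1.0)) < lr) z[i] = np;
      }
    }
  }

  // ---- coefficient / indicator updates ---------------------------------
  template <typename F>
  void update_block(SubModel& sm, double& f_cur, F lik) {
    int P = sm.P();
    // intercept
    {
      double prop = sm.b0 + sm.adapt.sd(0) * R::norm_rand();
      double shift = prop - sm.b0;
      for (int i = 0; i < S; i++) scratch[i] = sm.lp[i] + shift;
      double f_new = lik(scratch);
      double lr = f_new - f_cur + tprior.logd(prop) - tprior.logd(sm.b0);
      bool acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) { sm.b0 = prop; sm.lp.swap(scratch); f_cur = f_new; }
      sm.adapt.update(0, acc);
    }
    for (int m = 0; m < P; m++) {
      if (!sm.w[m]) {
        // excluded: the full conditional of the coefficient is its prior
        sm.b[m] = tprior.draw();
      } else {
        double prop = sm.b[m] + sm.adapt.sd(m + 1) * R::norm_rand();
        double d = prop - sm.b[m];
        for (int i = 0; i < S; i++) scratch[i] = sm.lp[i] + d * sm.X(i, m);
        double f_new = lik(scratch);
        double lr = f_new - f_cur + tprior.logd(prop) - tprior.logd(sm.b[m]);
        bool acc = std::log(R::runif(0.0, 1.0)) < lr;
        if (acc) { sm.b[m] = prop; sm.lp.swap(scratch); f_cur = f_new; }
        sm.adapt.update(m + 1, acc);
      }
    }
    // Kuo-Mallick indicators: Gibbs on the two-point conditional
    for (int m = 0; m < P; m++) {
      double sign = sm.w[m] ? -1.0 : 1.0;
      for (int i = 0; i < S; i++)
        scratch[i] = sm.lp[i] + sign * sm.b[m] * sm.X(i, m);
      double f_other = lik(scratch);
      double l1 = sm.w[m] ? f_cur : f_other;
      double l0 = sm.w[m] ? f_other : f_cur;
      double lo = l1 - l0 + logit_incl;
      int w_new = (R::runif(0.0, 1.0) < 1.0 / (1.0 + std::exp(-lo))) ? 1 : 0;
      if (w_new != sm.w[m]) {
        sm.w[m] = w_new;
        sm.lp.swap(scratch);
        f_cur = f_other;
      }
    }
  }

  // ---- random effects ---------------------------------------------------
  double eps_site_lik(int i, double e) const {
    if (family == 0) {
      if (!z[i]) return 0.0;
      return lbinom_logit(y2[i], k2, cam.lp[i] + e);
    }
    double ll = occ.lp[i] + e;
    return z[i] * ll - std::exp(ll);
  }
  void update_eps() {
    int acc_n = 0;
    for (int i = 0; i < S; i++) {
      double prop = eps[i] + adapt_eps.sd(0) * R::norm_rand();
      double lr = eps_site_lik(i, prop) - eps_site_lik(i, eps[i]) -
        0.5 * (prop * prop - eps[i] * eps[i]) / (sigma_eps * sigma_eps);
      if (std::log(R::runif(0.0, 1.0)) < lr) { eps[i] = prop; acc_n++; }
    }
    // tune on the average acceptance over sites
    adapt_eps.update(0, acc_n * 2 > S);
  }
  void update_sigma_eps() {
    double prop = sigma_eps + adapt_sig.sd(0) * R::norm_rand();
    bool acc = false;
    if (prop > 0.0 && prop < sd_upper) {
      double ss = 0.0;
      for (int i = 0; i < S; i++) ss += eps[i] * eps[i];
      double lr = -S * std::log(prop) - 0.5 * ss / (prop * prop) +
        S * std::log(sigma_eps) + 0.5 * ss / (sigma_eps * sigma_eps);
      acc = std::log(R::runif(0.0, 1.0)) < lr;
      if (acc) sigma_eps = prop;
    }
    adapt_sig.update(0, acc);
  }

  void sweep() {
    if (family == 0) update_z_basic(); else update_N();
    if (re) { update_eps(); update_sigma_eps(); }
    refresh_liks();   // latent / eps moves invalidate cached block liks
    update_block(occ, f_occ, [this](const std::vector<double>& lp) {
      return occ_lik(lp); });
    update_block(chev, f_chev, [this](const std::vector<double>& lp) {
      return chev_lik(lp); });
    update_block(cam, f_cam, [this](const std::vector<double>& lp) {
      return cam_lik(lp); });
  }
};

// [[Rcpp::export]]
List run_chain_cpp(int family, IntegerVector y1, IntegerVector y2, int k2,
                   NumericMatrix Xocc, NumericMatrix Xchev,
                   NumericMatrix Xcam, bool random_effect, int n_iter,
                   int burn_in, int thin, double t_sigma, double t_nu,
                   double sd_upper, double incl_prior, int N_max) {
  Sampler s(family, y1, y2, k2, Xocc, Xchev, Xcam, random_effect, t_sigma,
            t_nu, sd_upper, incl_prior, N_max);
  int P_occ = s.occ.P(), P1 = s.chev.P(), P2 = s.cam.P();
  int n_keep = (n_iter - burn_in) / thin;
  if (n_keep <= 0) stop("no retained draws: check n_iter / burn_in / thin");
  int n_par = (1 + P_occ) + (1 + P1) + (1 + P2) + P_occ + P1 + P2 + 2;
  NumericMatrix draws(n_keep, n_par);
  int row = 0;
  for (int it = 1; it <= n_iter; it++) {
    if (it == burn_in + 1) {
      // freeze proposal adaptation at the end of burn-in
      s.occ.adapt.frozen = s.chev.adapt.frozen = s.cam.adapt.frozen = true;
      s.adapt_eps.frozen = s.adapt_sig.frozen = true;
    }
    s.sweep();
    if (it > burn_in && (it - burn_in) % thin == 0) {
      int c = 0;
      draws(row, c++) = s.occ.b0;
      for (int m = 0; m < P_occ; m++) draws(row, c++) = s.occ.b[m];
      draws(row, c++) = s.chev.b0;
      for (int m = 0; m < P1; m++) draws(row, c++) = s.chev.b[m];
      draws(row, c++) = s.cam.b0;
      for (int m = 0; m < P2; m++) draws(row, c++) = s.cam.b[m];
      for (int m = 0; m < P_occ; m++) draws(row, c++) = s.occ.w[m];
      for (int m = 0; m < P1; m++) draws(row, c++) = s.chev.w[m];
      for (int m = 0; m < P2; m++) draws(row, c++) = s.cam.w[m];
      draws(row, c++) = s.sigma_eps;
      double lm = 0.0;
      for (int i = 0; i < s.S; i++) lm += s.z[i];
      draws(row, c++) = (s.S > 0) ? lm / s.S : NA_REAL;
      row++;
    }
  }
  return List::create(_["draws"] = draws);
}
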