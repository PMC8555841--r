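// Adaptive random-walk Metropolis-within-Gibbs sampler for the
// single-country prevalence state-space model.
//
// State: theta = (logit_ptilde, omega_l, phi_l, tau_l,
//                 omega_r, phi_r, tau_r, eta0, zeta0)
// plus non-centred distortion innovations xiL[0..T-1], xiR[0..T-1]
// (xi[0] scales the stationary initial distortion, xi[t>0] the AR(1)
// innovations). Constant drift on the transformed scale gives logistic
// growth toward the asymptote; surveys enter via normal densities on
// log-ratios, EMU series via normal densities on first differences of mCPR.

#include <Rcpp.h>
using namespace Rcpp;

static inline double invlogit(double x) {
  if (x >= 0.0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

struct Problem {
  int T;
  std::vector<int> st;                     // survey year index (0-based)
  std::vector<double> y1, y2, sd1, sd2;    // observed log-ratios and sds
  std::vector<int> e_to, e_from;           // EMU pair year indices
  std::vector<double> dz, esd;             // EMU differences and sds
  double p_mean, p_sd, omL_mean, omL_sd, omR_mean, omR_sd;
  double phi_max, tau_scale, eta0_mean, eta0_sd, zeta0_mean, zeta0_sd;
  std::vector<bool> fixed;                 // per-theta-coordinate
};

static double logpost(const Problem& P, const std::vector<double>& th,
                      const std::vector<double>& xiL,
                      const std::vector<double>& xiR,
                      std::vector<double>& L, std::vector<double>& R,
                      std::vector<double>& rho) {
  const double phiL = th[2], tauL = th[3], phiR = th[5], tauR = th[6];
  if (phiL < 0.0 || phiL >= P.phi_max || phiR < 0.0 || phiR >= P.phi_max)
    return R_NegInf;
  if (tauL < 0.0 || tauR < 0.0) return R_NegInf;

  double lp = 0.0;
  lp += R::dnorm(th[0], P.p_mean, P.p_sd, 1);
  lp += R::dnorm(th[1], P.omL_mean, P.omL_sd, 1);
  lp += R::dnorm(th[4], P.omR_mean, P.omR_sd, 1);
  lp += R::dnorm(tauL, 0.0, P.tau_scale, 1);  // half-normal up to a constant
  lp += R::dnorm(tauR, 0.0, P.tau_scale, 1);
  lp += R::dnorm(th[7], P.eta0_mean, P.eta0_sd, 1);
  lp += R::dnorm(th[8], P.zeta0_mean, P.zeta0_sd, 1);

  const int T = P.T;
  for (int t = 0; t < T; ++t)
    lp += R::dnorm(xiL[t], 0.0, 1.0, 1) + R::dnorm(xiR[t], 0.0, 1.0, 1);

  const double ptil = invlogit(th[0]);
  double eps = tauL / std::sqrt(1.0 - phiL * phiL) * xiL[0];
  double eta = th[7];
  L[0] = ptil * invlogit(eta);
  for (int t = 1; t < T; ++t) {
    eps = phiL * eps + tauL * xiL[t];
    eta += th[1] + eps;
    L[t] = ptil * invlogit(eta);
  }
  eps = tauR / std::sqrt(1.0 - phiR * phiR) * xiR[0];
  double zeta = th[8];
  R[0] = invlogit(zeta);
  for (int t = 1; t < T; ++t) {
    eps = phiR * eps + tauR * xiR[t];
    zeta += th[4] + eps;
    R[t] = invlogit(zeta);
  }
  for (int t = 0; t < T; ++t) rho[t] = L[t] * R[t];

  for (size_t i = 0; i < P.st.size(); ++i) {
    const int t = P.st[i];
    const double m = rho[t], none = 1.0 - L[t], tr = L[t] - rho[t];
    if (m <= 0.0 || tr <= 0.0 || none <= 0.0) return R_NegInf;
    lp += R::dnorm(P.y1[i], std::log(m) - std::log(none), P.sd1[i], 1);
    lp += R::dnorm(P.y2[i], std::log(tr) - std::log(none), P.sd2[i], 1);
  }
  for (size_t i = 0; i < P.e_to.size(); ++i)
    lp += R::dnorm(P.dz[i], rho[P.e_to[i]] - rho[P.e_from[i]], P.esd[i], 1);
  return lp;
}

// [[Rcpp::export]]
List run_mcmc_chain(List data, int warmup, int iter,
                    NumericVector th0, NumericVector xiL0,
                    NumericVector xiR0) {
  Problem P;
  P.T = as<int>(data["T"]);
  P.st = as<std::vector<int>>(data["surv_t"]);
  P.y1 = as<std::vector<double>>(data["surv_y1"]);
  P.y2 = as<std::vector<double>>(data["surv_y2"]);
  P.sd1 = as<std::vector<double>>(data["surv_sd1"]);
  P.sd2 = as<std::vector<double>>(data["surv_sd2"]);
  P.e_to = as<std::vector<int>>(data["emu_to"]);
  P.e_from = as<std::vector<int>>(data["emu_from"]);
  P.dz = as<std::vector<double>>(data["emu_dz"]);
  P.esd = as<std::vector<double>>(data["emu_sd"]);
  P.p_mean = as<double>(data["p_mean"]);     P.p_sd = as<double>(data["p_sd"]);
  P.omL_mean = as<double>(data["omL_mean"]); P.omL_sd = as<double>(data["omL_sd"]);
  P.omR_mean = as<double>(data["omR_mean"]); P.omR_sd = as<double>(data["omR_sd"]);
  P.phi_max = as<double>(data["phi_max"]);
  P.tau_scale = as<double>(data["tau_scale"]);
  P.eta0_mean = as<double>(data["eta0_mean"]);   P.eta0_sd = as<double>(data["eta0_sd"]);
  P.zeta0_mean = as<double>(data["zeta0_mean"]); P.zeta0_sd = as<double>(data["zeta0_sd"]);
  LogicalVector fx = data["fixed"];
  for (int k = 0; k < 9; ++k) P.fixed.push_back(fx[k] == TRUE);

  const int T = P.T;
  std::vector<double> th(th0.begin(), th0.end());
  std::vector<double> xiL(xiL0.begin(), xiL0.end());
  std::vector<double> xiR(xiR0.begin(), xiR0.end());
  std::vector<double> L(T), R(T), rho(T), Lp(T), Rp(T), rhop(T);

  // distortions are sampled only when their scale can be non-zero
  const bool upL = !(P.fixed[3] && th[3] == 0.0);
  const bool upR = !(P.fixed[6] && th[6] == 0.0);

  double cur = logpost(P, th, xiL, xiR, L, R, rho);
  if (!R_finite(cur)) stop("initial state has zero posterior density");

  std::vector<double> lsT(9, std::log(0.1)), lsL(T, std::log(0.5)),
      lsR(T, std::log(0.5));
  NumericMatrix theta_s(iter, 9), rho_s(iter, T), cpr_s(iter, T),
      ratio_s(iter, T);
  std::vector<double> accT(9, 0.0);
  long propT = 0;

  const int total = warmup + iter;
  for (int s = 0; s < total; ++s) {
    const bool adapt = s < warmup;
    const double g = std::min(0.25, 2.0 / std::sqrt((double)(s + 1)));

    for (int k = 0; k < 9; ++k) {
      if (P.fixed[k]) continue;
      const double old = th[k];
      th[k] = old + std::exp(lsT[k]) * norm_rand();
      const double prop = logpost(P, th, xiL, xiR, Lp, Rp, rhop);
      const double a = std::min(1.0, std::exp(prop - cur));
      if (unif_rand() < a) {
        cur = prop; L.swap(Lp); R.swap(Rp); rho.swap(rhop);
        if (!adapt) accT[k] += 1.0;
      } else th[k] = old;
      if (adapt) lsT[k] += g * (a - 0.44);
    }
    if (upL) {
      for (int t = 0; t < T; ++t) {
        const double old = xiL[t];
        xiL[t] = old + std::exp(lsL[t]) * norm_rand();
        const double prop = logpost(P, th, xiL, xiR, Lp, Rp, rhop);
        const double a = std::min(1.0, std::exp(prop - cur));
        if (unif_rand() < a) { cur = prop; L.swap(Lp); R.swap(Rp); rho.swap(rhop); }
        else xiL[t] = old;
        if (adapt) lsL[t] += g * (a - 0.44);
      }
    }
    if (upR) {
      for (int t = 0; t < T; ++t) {
        const double old = xiR[t];
        xiR[t] = old + std::exp(lsR[t]) * norm_rand();
        const double prop = logpost(P, th, xiL, xiR, Lp, Rp, rhop);
        const double a = std::min(1.0, std::exp(prop - cur));
        if (unif_rand() < a) { cur = prop; L.swap(Lp); R.swap(Rp); rho.swap(rhop); }
        else xiR[t] = old;
        if (adapt) lsR[t] += g * (a - 0.44);
      }
    }
    if (s >= warmup) {
      const int i = s - warmup;
      ++propT;
      for (int k = 0; k < 9; ++k) theta_s(i, k) = th[k];
      for (int t = 0; t < T; ++t) {
        rho_s(i, t) = rho[t]; cpr_s(i, t) = L[t]; ratio_s(i, t) = R[t];
      }
    }
  }
  NumericVector acc(9);
  for (int k = 0; k < 9; ++k)
    acc[k] = propT > 0 ? accT[k] / (double)propT : NA_REAL;
  return List::create(_["theta"] = theta_s, _["rho"] = rho_s,
                      _["cpr"] = cpr_s, _["ratio"] = ratio_s,
                      _["accept_theta"] = acc);
}
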