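// Forward choice-probability engine.
//
// Computes the per-trial probability that the focal player picks option 1
// under each learner, running the model deterministically along a recorded
// pair of action sequences. This is the hot path of model inversion (one
// call per likelihood evaluation inside the optimizer), so it mirrors the
// R agent implementations exactly; an equivalence test in the test suite
// keeps the two paths aligned.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// 21-node Gauss-Hermite rule (nodes; weights normalized by 1/sqrt(pi)),
// identical to the rule computed at load time on the R side.
static const double GHN[21] = {
  5.5503518732646784, 4.7739923434112193, 4.1219955474918404,
  3.5319728771376782, 2.9799912077045989, 2.4535521245128389,
  1.9449629491862535, 1.4489342506507317, 0.96149963441837016,
  0.47945070707910808, 0.0, -0.47945070707910542, -0.96149963441836661,
  -1.4489342506507281, -1.9449629491862535, -2.4535521245128384,
  -2.9799912077046011, -3.5319728771376733, -4.1219955474918413,
  -4.7739923434112166, -5.5503518732646837};
static const double GHW[21] = {
  2.0989912195656659e-14, 4.9753686041217716e-11, 1.4506612844930794e-08,
  1.2253548361482494e-06, 4.2192347425516611e-05, 0.00070804779548153866,
  0.0064396970514088506, 0.033952729786543172, 0.10839228562641998,
  0.21533371569505813, 0.27026018357287451, 0.21533371569506055,
  0.10839228562642078, 0.033952729786542526, 0.0064396970514086216,
  0.00070804779548152999, 4.2192347425515147e-05, 1.2253548361482344e-06,
  1.4506612844930316e-08, 4.9753686041216831e-11, 2.0989912195654466e-14};

static inline double sgm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static void sg_both(double mu, double v, double &p, double &dp) {
  if (v <= 0.0) {
    double s = sgm(mu);
    p = s; dp = s * (1.0 - s);
    return;
  }
  double s2 = std::sqrt(2.0 * v);
  p = 0.0; dp = 0.0;
  for (int i = 0; i < 21; ++i) {
    double s = sgm(mu + s2 * GHN[i]);
    p += GHW[i] * s;
    dp += GHW[i] * s * (1.0 - s);
  }
}

static inline double sg(double mu, double v) {
  double p, dp; sg_both(mu, v, p, dp); return p;
}

static inline double logit_c(double p) {
  p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
  return std::log(p / (1.0 - p));
}

static inline void tom0_step(double &mu, double &sig, int obs, double vol) {
  double sp = sig + vol;
  double s = sgm(mu);
  double sn = 1.0 / (1.0 / sp + s * (1.0 - s));
  mu += sn * (obs - s);
  sig = sn;
}

// payoff helpers; u is the 2x2x2 table flattened R-style: idx = r + 2a + 4b
static inline double pay(const double *u, int r, int a, int b) {
  return u[r + 2 * a + 4 * b];
}
static inline double vd0(const double *u, int r) {  // dv when b = 0
  return pay(u, r, 1, 0) - pay(u, r, 0, 0);
}
static inline double vd1(const double *u, int r) {  // dv when b = 1
  return pay(u, r, 1, 1) - pay(u, r, 0, 1);
}

// ---------------- recursive k-ToM state ----------------

struct Ktom {
  int k;                       // 0 = frequency tracker
  double vol, temp, bias;
  double mu0, sig0;            // 0-ToM belief
  struct Level {
    int j;
    double mu[3], sig[3], vq;  // (q, log-vol, log-temp) beliefs
    Ktom *sim;
  };
  std::vector<double> lp;
  std::vector<Level> lev;
  double d0_opp, d1_opp, d0_own, d1_own;

  Ktom(int k_, int role, const double *u, double vol_, double temp_,
       double bias_)
      : k(k_), vol(vol_), temp(temp_), bias(bias_), mu0(0.0), sig0(1.0) {
    int orole = 1 - role;
    d0_own = vd0(u, role); d1_own = vd1(u, role);
    d0_opp = vd0(u, orole); d1_opp = vd1(u, orole);
    if (k >= 1) {
      lp.assign(k, 1.0 / k);
      lev.resize(k);
      for (int j = 0; j < k; ++j) {
        Level &lv = lev[j];
        lv.j = j;
        lv.mu[0] = 0.0;                 // like-me prior on the opponent
        lv.mu[1] = std::log(vol_);
        lv.mu[2] = std::log(temp_);
        lv.sig[0] = lv.sig[1] = lv.sig[2] = 1.0;
        lv.vq = 1.0;
        lv.sim = (j >= 1) ? new Ktom(j, orole, u, vol_, temp_, 0.0) : nullptr;
      }
    }
  }
  ~Ktom() {
    for (size_t j = 0; j < lev.size(); ++j) delete lev[j].sim;
  }

  void levelPred(const Level &lv, double &p1, double &f, double g[3]) const {
    double pm, dpm;
    sg_both(lv.mu[0], lv.vq, pm, dpm);
    double eb = std::exp(lv.mu[2]);
    f = (d0_opp + (d1_opp - d0_opp) * pm) / eb;
    g[0] = (d1_opp - d0_opp) * dpm / eb;
    g[1] = 0.0;
    g[2] = -f;
    double var_f = g[0] * g[0] * lv.sig[0] + f * f * lv.sig[2];
    p1 = sg(f, var_f);
  }

  double predict() const {  // P(opponent plays 1)
    if (k == 0) return sg(mu0, sig0);
    double p = 0.0, f, g[3], p1;
    for (int j = 0; j < k; ++j) {
      levelPred(lev[j], p1, f, g);
      p += lp[j] * p1;
    }
    return p;
  }

  double choiceProb() const {
    double p_opp = predict();
    double dv = d0_own + (d1_own - d0_own) * p_opp;
    return sgm(dv / temp + bias);
  }

  void update(int own, int opp) {
    if (k == 0) {
      tom0_step(mu0, sig0, opp, vol);
      return;
    }
    std::vector<double> f(k), p1(k);
    std::vector<std::array<double, 3> > g(k);
    double tot = 0.0;
    for (int j = 0; j < k; ++j) {
      levelPred(lev[j], p1[j], f[j], g[j].data());
      double lik = (opp == 1) ? p1[j] : 1.0 - p1[j];
      lp[j] *= std::max(lik, 1e-12);
      tot += lp[j];
    }
    for (int j = 0; j < k; ++j) lp[j] /= tot;

    for (int j = 0; j < k; ++j) {
      double w = lp[j];
      if (w <= 0.0) continue;
      Level &lv = lev[j];
      double s = sgm(f[j]);
      for (int i = 0; i < 3; ++i) {
        double sig_pred = lv.sig[i] + (i == 0 ? w * vol : 0.0);
        double gi = g[j][i];
        double sig_new = 1.0 / (1.0 / sig_pred + w * gi * gi * s * (1.0 - s));
        lv.mu[i] += w * sig_new * gi * (opp - s);
        lv.sig[i] = sig_new;
      }
      if (lv.j == 0) {
        tom0_step(lv.mu[0], lv.vq, own, std::exp(lv.mu[1]));
      } else {
        lv.sim->vol = std::exp(lv.mu[1]);
        lv.sim->temp = std::exp(lv.mu[2]);
        double q_old = logit_c(lv.sim->predict());
        lv.sim->update(opp, own);
        lv.mu[0] += logit_c(lv.sim->predict()) - q_old;
      }
    }
  }
};

// ---------------- flat baseline learners ----------------

static double par(const List &p, const char *nm) {
  return as<double>(p[nm]);
}

// [[Rcpp::export(name = ".cpp_choice_path")]]
NumericVector cpp_choice_path(std::string model, List params,
                              IntegerVector a_self, IntegerVector a_opp,
                              NumericVector payoff_u, int role) {
  int T = a_self.size();
  NumericVector out(T);
  const double *u = payoff_u.begin();
  double d0 = vd0(u, role), d1 = vd1(u, role);
  double bias = params.containsElementNamed("bias") ? par(params, "bias") : 0.0;

  if (model == "Nash") {
    double p = sgm(bias);
    std::fill(out.begin(), out.end(), p);
    return out;
  }

  if (model == "WSLS") {
    double temp = par(params, "temperature");
    double umax = 0.0;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) umax = std::max(umax, pay(u, role, a, b));
    int last_choice = -1, last_outcome = -1;
    for (int t = 0; t < T; ++t) {
      double dv = 0.0;
      if (last_choice >= 0) {
        int target = (last_outcome == 1) ? last_choice : 1 - last_choice;
        dv = (target == 1) ? 1.0 : -1.0;
      }
      out[t] = sgm(dv / temp + bias);
      last_choice = a_self[t];
      last_outcome = (pay(u, role, a_self[t], a_opp[t]) == umax) ? 1 : 0;
    }
    return out;
  }

  if (model == "RL") {
    double temp = par(params, "temperature"), alpha = par(params, "alpha");
    double v[2] = {0.5, 0.5};
    for (int t = 0; t < T; ++t) {
      out[t] = sgm((v[1] - v[0]) / temp + bias);
      double reward = pay(u, role, a_self[t], a_opp[t]);
      v[a_self[t]] += alpha * (reward - v[a_self[t]]);
    }
    return out;
  }

  if (model == "1-BSL" || model == "2-BSL" || model == "3-BSL") {
    int n = model[0] - '0';
    double temp = par(params, "temperature"), vol = par(params, "volatility");
    int ncell = 1 << n;
    std::vector<double> mu(ncell, 0.0), sig(ncell, 1.0);
    std::vector<int> hist;  // oldest first
    for (int t = 0; t < T; ++t) {
      double p_opp = 0.5;
      if ((int)hist.size() == n) {
        int idx = 0;
        for (int i = 0; i < n; ++i) idx += hist[i] << i;
        p_opp = sg(mu[idx], sig[idx]);
      }
      double dv = d0 + (d1 - d0) * p_opp;
      out[t] = sgm(dv / temp + bias);
      if ((int)hist.size() == n) {
        int idx = 0;
        for (int i = 0; i < n; ++i) idx += hist[i] << i;
        tom0_step(mu[idx], sig[idx], a_opp[t], vol);
        hist.erase(hist.begin());
      }
      hist.push_back(a_opp[t]);
    }
    return out;
  }

  if (model == "hBL") {
    double temp = par(params, "temperature");
    double kap = par(params, "kappa"), om = par(params, "omega"),
           th = par(params, "theta");
    double mu2 = 0.0, sigma2 = 1.0, mu3 = 0.0, sigma3 = 1.0;
    for (int t = 0; t < T; ++t) {
      double e2 = std::min(std::max(kap * mu3 + om, -30.0), 30.0);
      double v2 = std::exp(e2);
      double p_opp = sg(mu2, sigma2 + v2);
      double dv = d0 + (d1 - d0) * p_opp;
      out[t] = sgm(dv / temp + bias);

      int obs = a_opp[t];
      double muhat1 = sgm(mu2);
      double pihat2 = 1.0 / (sigma2 + v2);
      double pi2 = pihat2 + muhat1 * (1.0 - muhat1);
      double mu2n = mu2 + (obs - muhat1) / pi2;
      double sigma2n = 1.0 / pi2;
      double pihat3 = 1.0 / (sigma3 + th);
      double w2 = v2 * pihat2;
      double r2 = (v2 - sigma2) * pihat2;
      double delta2 = (sigma2n + (mu2n - mu2) * (mu2n - mu2)) * pihat2 - 1.0;
      double pi3 = pihat3 + (kap * kap / 2.0) * w2 * (w2 + r2 * delta2);
      pi3 = std::max(pi3, 1e-6);
      mu3 += (kap / 2.0) * (w2 / pi3) * delta2;
      sigma3 = 1.0 / pi3;
      mu2 = mu2n; sigma2 = sigma2n;
    }
    return out;
  }

  if (model == "1-Inf" || model == "2-Inf") {
    int order = model[0] - '0';
    double eta1 = par(params, "eta1"), eta2 = par(params, "eta2");
    double eta3 = (order == 2) ? par(params, "eta3") : 0.0;
    int orole = 1 - role;
    double sgn_opp = ((vd1(u, orole) - vd0(u, orole)) > 0) ? 1.0 : -1.0;
    double sgn_self = ((d1 - d0) > 0) ? 1.0 : -1.0;
    const double eps = 1e-6;
    double p = 0.5, q = 0.5;
    for (int t = 0; t < T; ++t) {
      double dv = d0 + (d1 - d0) * p;
      out[t] = sgm(dv + bias);  // unit softmax slope
      double ope = a_self[t] - q;
      double pn = p + eta1 * (a_opp[t] - p) + eta2 * sgn_opp * ope;
      double qn = q + eta1 * ope;
      if (order == 2) qn += eta3 * sgn_self * (a_opp[t] - p);
      p = std::min(std::max(pn, eps), 1.0 - eps);
      q = std::min(std::max(qn, eps), 1.0 - eps);
    }
    return out;
  }

  // k-ToM family: "0-ToM" .. "3-ToM"
  if (model.size() == 5 && model.substr(1) == "-ToM") {
    int k = model[0] - '0';
    double temp = par(params, "temperature"), vol = par(params, "volatility");
    Ktom ag(k, role, u, vol, temp, bias);
    for (int t = 0; t < T; ++t) {
      out[t] = ag.choiceProb();
      ag.update(a_self[t], a_opp[t]);
    }
    return out;
  }

  stop("unknown model '%s'", model.c_str());
  return out;  // not reached
}
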