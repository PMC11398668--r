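#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hodgkin-Huxley channel rate constants (1/ms). The two alpha terms have
// removable singularities at V = -20 and V = -16 mV; evaluated by their
// analytic limits when within 1e-6 mV.
static inline void hh_rates(double V, double *r) {
  double u = V + 20.0;
  r[0] = (std::fabs(u) < 1e-6) ? 0.1 : 0.01 * u / (1.0 - std::exp(-u / 10.0));
  r[1] = 0.125 * std::exp(-(V + 30.0) / 80.0);
  u = V + 16.0;
  r[2] = (std::fabs(u) < 1e-6) ? 1.0 : 0.1 * u / (1.0 - std::exp(-u / 10.0));
  r[3] = 4.0 * std::exp(-(V + 41.0) / 18.0);
  r[4] = 0.07 * std::exp(-(V + 30.0) / 20.0);
  r[5] = 1.0 / (1.0 + std::exp(-V / 10.0));
}

// [[Rcpp::export]]
NumericVector hh_rate_constants_cpp(double V) {
  if (!R_finite(V)) stop("membrane potential must be finite");
  double r[6];
  hh_rates(V, r);
  NumericVector out(6);
  for (int k = 0; k < 6; ++k) out[k] = r[k];
  out.attr("names") = CharacterVector::create("alpha_n", "beta_n", "alpha_m",
                                              "beta_m", "alpha_h", "beta_h");
  return out;
}

struct HHPar {
  double Cm, gK, gNa, gL, EK, ENa, EL;
};

static inline void hh_deriv(const double *s, double I, const HHPar &p,
                            double *ds) {
  double V = s[0], n = s[1], m = s[2], h = s[3];
  double r[6];
  hh_rates(V, r);
  double n4 = n * n * n * n;
  double m3 = m * m * m;
  ds[0] = (-p.gK * n4 * (V - p.EK) - p.gNa * m3 * h * (V - p.ENa) -
           p.gL * (V - p.EL) + I) / p.Cm;
  ds[1] = r[0] * (1.0 - n) - r[1] * n;
  ds[2] = r[2] * (1.0 - m) - r[3] * m;
  ds[3] = r[4] * (1.0 - h) - r[5] * h;
}

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// One fixed-step RK4 advance of (V, n, m, h) under current I held constant.
static inline void hh_rk4(double *s, double I, const HHPar &p, double dt) {
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  hh_deriv(s, I, p, k1);
  for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
  hh_deriv(tmp, I, p, k2);
  for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
  hh_deriv(tmp, I, p, k3);
  for (int j = 0; j < 4; ++j) tmp[j] = s[j] + dt * k3[j];
  hh_deriv(tmp, I, p, k4);
  for (int j = 0; j < 4; ++j)
    s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  s[1] = clip01(s[1]);
  s[2] = clip01(s[2]);
  s[3] = clip01(s[3]);
}

// Single-neuron integration with an injected current trace (length 1 =
// constant).  Spikes are upward crossings of 0 mV with a 2 ms minimum
// inter-spike interval.
// [[Rcpp::export]]
List hh_simulate_cpp(NumericVector par, NumericVector I, double dt,
                     int n_steps, NumericVector init, bool record_v) {
  if (dt <= 0) stop("dt must be positive");
  HHPar p = {par[0], par[1], par[2], par[3], par[4], par[5], par[6]};
  double s[4] = {init[0], init[1], init[2], init[3]};
  bool const_I = (I.size() == 1);
  std::vector<double> vtrace;
  if (record_v) vtrace.reserve(n_steps + 1);
  if (record_v) vtrace.push_back(s[0]);
  std::vector<double> spikes;
  double last_spike = -1e9, v_prev = s[0];
  for (int k = 0; k < n_steps; ++k) {
    double Ik = const_I ? I[0] : I[k];
    hh_rk4(s, Ik, p, dt);
    if (!R_finite(s[0]))
      stop("integration failure: non-finite membrane potential at step %d", k + 1);
    double t = (k + 1) * dt;
    if (v_prev < 0.0 && s[0] >= 0.0 && (t - last_spike) > 2.0) {
      spikes.push_back(t);
      last_spike = t;
    }
    v_prev = s[0];
    if (record_v) vtrace.push_back(s[0]);
  }
  List out = List::create(
      _["spikes"] = wrap(spikes),
      _["state"] = NumericVector::create(_["V"] = s[0], _["n"] = s[1],
                                         _["m"] = s[2], _["h"] = s[3]));
  if (record_v) out["V"] = wrap(vtrace);
  return out;
}

// Piecewise-linear lookup of the six rate constants and the Mg-block
// factor on a fine voltage grid; used by the network integrator where the
// rate functions dominate runtime. Grid 0.02 mV over [-130, 80] mV keeps
// the interpolation error orders of magnitude below the integration error;
// outside the grid the exact functions are used.
struct RateTable {
  double v_lo, v_hi, dv, inv_dv, Mg;
  std::vector<double> r[6];
  std::vector<double> B;
  void init(double Mg_) {
    v_lo = -130.0;
    v_hi = 80.0;
    dv = 0.02;
    inv_dv = 1.0 / dv;
    Mg = Mg_;
    int n = (int)std::lround((v_hi - v_lo) / dv) + 1;
    for (int k = 0; k < 6; ++k) r[k].resize(n);
    B.resize(n);
    double rv[6];
    for (int i = 0; i < n; ++i) {
      double V = v_lo + i * dv;
      hh_rates(V, rv);
      for (int k = 0; k < 6; ++k) r[k][i] = rv[k];
      B[i] = 1.0 / (1.0 + Mg * std::exp(-0.062 * V) / 3.57);
    }
  }
  inline void rates(double V, double *out, double *Bout) const {
    if (V <= v_lo || V >= v_hi) {
      hh_rates(V, out);
      *Bout = 1.0 / (1.0 + Mg * std::exp(-0.062 * V) / 3.57);
      return;
    }
    double u = (V - v_lo) * inv_dv;
    int i = (int)u;
    double f = u - i;
    for (int k = 0; k < 6; ++k)
      out[k] = r[k][i] + f * (r[k][i + 1] - r[k][i]);
    *Bout = B[i] + f * (B[i + 1] - B[i]);
  }
};

// Delayed match-to-sample trial on the two-area network.
//
// Synaptic bookkeeping exploits linearity of the AMPA/GABA gating ODEs:
// the per-receiver summed gating S_i = sum_j eps_ij s_j obeys the same
// exponential decay as each s_j, so it is tracked directly and incremented
// by w per afferent spike (event-driven).  NMDA gating saturates per
// presynaptic neuron (ds/dt = -s/tau_d + alpha x (1-s)), so it is kept per
// presynaptic pyramidal cell and summed across each receiver's afferents
// every step.  Background drive enters a per-neuron external-AMPA gating
// trace as an independent Poisson event train (rate nu_ext, increment D_p).
//
// M_rec: within-area adjacency (row = receiver), block structure supplied
// by the caller; M_ext: between-area adjacency.  type: 1 = pyramidal,
// 2 = interneuron; area: 1 = sensory, 2 = association.
// [[Rcpp::export]]
List run_trial_cpp(IntegerMatrix M_rec, IntegerMatrix M_ext,
                   IntegerVector type, IntegerVector area,
                   NumericVector neuron_par, NumericVector syn_par,
                   NumericVector noise_par, NumericVector proto, double dt) {
  int N = M_rec.nrow();
  if (M_rec.ncol() != N || M_ext.nrow() != N || M_ext.ncol() != N ||
      type.size() != N || area.size() != N)
    stop("adjacency/label dimensions disagree");
  if (dt <= 0) stop("dt must be positive");

  // neuron_par: Cm_E, Cm_I, gK, gNa, gL, EK, ENa, EL
  HHPar pE = {neuron_par[0], neuron_par[2], neuron_par[3], neuron_par[4],
              neuron_par[5], neuron_par[6], neuron_par[7]};
  HHPar pI = pE;
  pI.Cm = neuron_par[1];

  // syn_par: gAext, gA, gN, gG, VE, VI, tauA, tauNr, tauNd, tauG, Mg,
  //          alpha, w, w_ext
  double gAext = syn_par[0], gA = syn_par[1], gN = syn_par[2], gG = syn_par[3];
  double VE = syn_par[4], VI = syn_par[5];
  double tauA = syn_par[6], tauNr = syn_par[7], tauNd = syn_par[8],
         tauG = syn_par[9];
  double Mg = syn_par[10], alpha = syn_par[11], w = syn_par[12];
  double w_ext = syn_par[13], w_gaba = syn_par[14];
  // background conductance: unscaled by any fixture-size compensation
  double gAbg = syn_par[15];

  double nu = noise_par[0] / 1000.0;  // events per ms per neuron
  double Dp = noise_par[1];

  // proto: t_settle, t_precue, t_cue, t_delay, t_match, I_cue,
  //        t_reward_onset
  double t_settle = proto[0];
  double cue_on = proto[1], cue_off = proto[1] + proto[2];
  double match_on = cue_off + proto[3], match_off = match_on + proto[4];
  double I_cue = proto[5];
  double reward_on = match_on + proto[6];
  double t_end = match_off;
  int n_steps = (int)std::lround((t_settle + t_end) / dt);

  // adjacency lists from the presynaptic side
  std::vector<std::vector<int> > rec_tgt(N), ext_tgt(N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      if (M_rec(i, j)) rec_tgt[j].push_back(i);
      if (M_ext(i, j)) ext_tgt[j].push_back(i);
    }

  std::vector<double> V(N), n_(N), m_(N), h_(N);
  for (int i = 0; i < N; ++i) {
    // resting-equilibrium start (near E_L); settled further before t = 0
    V[i] = -65.0;
    double r[6];
    hh_rates(V[i], r);
    n_[i] = r[0] / (r[0] + r[1]);
    m_[i] = r[2] / (r[2] + r[3]);
    h_[i] = r[4] / (r[4] + r[5]);
  }
  std::vector<double> bg(N, 0.0), Sarec(N, 0.0), Saext(N, 0.0), Sgaba(N, 0.0);
  std::vector<double> snmda(N, 0.0), xnmda(N, 0.0), Snmda(N, 0.0);
  std::vector<double> last_spike(N, -1e9), v_prev(V);
  std::vector<double> t_next(N);
  for (int i = 0; i < N; ++i)
    t_next[i] = (nu > 0) ? R::exp_rand() / nu : R_PosInf;

  double dA = std::exp(-dt / tauA), dG = std::exp(-dt / tauG),
         dNr = std::exp(-dt / tauNr);

  RateTable tab;
  tab.init(Mg);

  std::vector<int> ras_id;
  std::vector<double> ras_t;
  ras_id.reserve(20000);
  ras_t.reserve(20000);

  for (int k = 0; k < n_steps; ++k) {
    double t_abs = k * dt;           // time since integration start
    double t = t_abs - t_settle;     // protocol time

    // gating decay (exact for the linear traces, Euler for NMDA saturation)
    for (int i = 0; i < N; ++i) {
      bg[i] *= dA;
      Saext[i] *= dA;
      Sarec[i] *= dA;
      Sgaba[i] *= dG;
    }
    for (int j = 0; j < N; ++j) {
      if (type[j] == 1) {
        xnmda[j] *= dNr;
        double s = snmda[j];
        s += dt * (-s / tauNd + alpha * xnmda[j] * (1.0 - s));
        snmda[j] = clip01(s);
      }
    }
    // background Poisson events
    if (nu > 0)
      for (int i = 0; i < N; ++i)
        while (t_next[i] <= t_abs + dt) {
          bg[i] += Dp;
          t_next[i] += R::exp_rand() / nu;
        }
    // summed NMDA gating per receiver
    std::fill(Snmda.begin(), Snmda.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      if (type[j] != 1) continue;
      double sj = snmda[j];
      if (sj <= 0.0) continue;
      const std::vector<int> &tg = rec_tgt[j];
      for (size_t q = 0; q < tg.size(); ++q) Snmda[tg[q]] += sj;
    }

    bool cue_win = (t >= cue_on && t < cue_off);
    bool match_win = (t >= match_on && t < match_off);
    bool reward_win = (t >= reward_on && t < t_end);

    for (int i = 0; i < N; ++i) {
      double Istim = 0.0;
      if ((cue_win || match_win) && area[i] == 1 && type[i] == 1)
        Istim += I_cue;
      if (reward_win && area[i] == 2 && type[i] == 2) Istim += I_cue;

      double cA = gAbg * bg[i] + gAext * Saext[i] + gA * Sarec[i];
      double cN = gN * Snmda[i];
      double cG = gG * Sgaba[i];
      const HHPar &p = (type[i] == 1) ? pE : pI;

      // RK4 with synaptic conductances frozen over the step; the driving
      // force and Mg block follow the substep voltage
      double s[4] = {V[i], n_[i], m_[i], h_[i]};
      double k1[4], k2[4], k3[4], k4[4], tmp[4];
      double r[6];
      for (int stage = 0; stage < 4; ++stage) {
        const double *src = (stage == 0) ? s : tmp;
        double Vs = src[0];
        double B;
        tab.rates(Vs, r, &B);
        double Isyn =
            -(cA * (Vs - VE) + cN * B * (Vs - VE) + cG * (Vs - VI)) + Istim;
        double *ks = (stage == 0) ? k1 : (stage == 1) ? k2 : (stage == 2) ? k3
                                                                          : k4;
        double n4 = src[1] * src[1] * src[1] * src[1];
        double m3 = src[2] * src[2] * src[2];
        ks[0] = (-p.gK * n4 * (Vs - p.EK) - p.gNa * m3 * src[3] * (Vs - p.ENa) -
                 p.gL * (Vs - p.EL) + Isyn) / p.Cm;
        ks[1] = r[0] * (1.0 - src[1]) - r[1] * src[1];
        ks[2] = r[2] * (1.0 - src[2]) - r[3] * src[2];
        ks[3] = r[4] * (1.0 - src[3]) - r[5] * src[3];
        if (stage < 3) {
          double fac = (stage == 2) ? dt : 0.5 * dt;
          for (int j = 0; j < 4; ++j) tmp[j] = s[j] + fac * ks[j];
        }
      }
      for (int j = 0; j < 4; ++j)
        s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      V[i] = s[0];
      n_[i] = clip01(s[1]);
      m_[i] = clip01(s[2]);
      h_[i] = clip01(s[3]);
      if (!R_finite(V[i]))
        stop("integration failure: non-finite potential, neuron %d step %d",
             i + 1, k + 1);
    }

    // spike detection and event-driven transmission
    double t_now = (k + 1) * dt - t_settle;
    for (int i = 0; i < N; ++i) {
      if (v_prev[i] < 0.0 && V[i] >= 0.0 && (t_now - last_spike[i]) > 2.0) {
        last_spike[i] = t_now;
        if (t_now >= 0.0) {
          ras_id.push_back(i + 1);
          ras_t.push_back(t_now);
        }
        if (type[i] == 1) {
          xnmda[i] += w;
          const std::vector<int> &tg = rec_tgt[i];
          for (size_t q = 0; q < tg.size(); ++q) Sarec[tg[q]] += w;
          const std::vector<int> &te = ext_tgt[i];
          for (size_t q = 0; q < te.size(); ++q) Saext[te[q]] += w_ext;
        } else {
          const std::vector<int> &tg = rec_tgt[i];
          for (size_t q = 0; q < tg.size(); ++q) Sgaba[tg[q]] += w_gaba;
        }
      }
      v_prev[i] = V[i];
    }
  }

  return List::create(_["neuron"] = wrap(ras_id), _["time"] = wrap(ras_t),
                      _["t_end"] = t_end);
}
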