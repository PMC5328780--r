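// Fixed-step RK4 integrator for the three-leg neuromechanical network.
//
// All tunable quantities live in a flat parameter vector P whose layout is
// exported by sw_param_layout(); scheduled "events" rewrite single entries of
// P at given times, which is how decoupling commands, mode switches and
// sensory-independent perturbations are realised.  The continuous state is
// integrated with classical RK4; the discrete ground-contact / flexion
// latches and the phasic position-sense triggers are updated once per step
// from the beta/alpha crossings, so the whole simulation is bit-reproducible
// for identical inputs.

#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

// ---- parameter layout -------------------------------------------------------

static const char* kGlobalNames[] = {
  "C_cpg", "gL_cpg", "EL_cpg", "gP", "EP", "th_m", "sg_m", "th_h", "sg_h",
  "tauh0", "sg_th", "C_pas", "gL_pas", "EL_pas", "th_s", "sg_s", "E_inh", "E_exc",
  "g_cc", "g_cpg_in", "g_in_tone", "g_in_mn", "g_MN", "tau_act",
  "gain_alpha", "gain_beta", "gain_gamma", "tau_p", "g_sn",
  "g_snl_lev", "g_snl_dep", "g_snt_dep", "g_snt_lev", "g_gate",
  "beta_pr_th", "beta_ef_th", "hyst", "alpha_pro_th", "alpha_ret_th",
  "V_sanity", "th_t"
};
static const int NGLOB = 41;

// per-leg block, offsets relative to leg base
static const int P_GAPPE = 0;   // 6: excitatory drive g_app (E = E_exc)
static const int P_GAPPI = 6;   // 6: inhibitory drive (E = E_inh)
static const int P_GD    = 12;  // 6: tonic inhibition of premotor INs
static const int P_ISG   = 18;  // intersegmental max conductance
static const int P_ISTH  = 19;  // beta threshold of the mapping
static const int P_ISSL  = 20;  // slope (deg) of the mapping sigmoid
static const int P_ISE   = 21;  // reversal potential of the synapse
static const int P_ISFIX = 22;  // >0.5: constant strength is_g (bypass map)
static const int P_ISDG  = 23;  // >0.5: gate mapping on rising posterior beta
static const int P_EFINV = 24;  // >0.5: flexion during swing (metathorax)
static const int NPL = 25;

static const int NLEG = 3;                  // 0 = FL/pro, 1 = ML/meso, 2 = HL/meta
static const int NPAR = NGLOB + NLEG * NPL; // 114

// ---- state layout (per leg, stride 37) -------------------------------------
// 0..5  V of CPG neurons (pro, ret, lev, dep, ext, flex)
// 6..11 h of CPG neurons
// 12..17 V of premotor INs (same muscle order)
// 18..19 V of sensory INs (0 = lift signal, 1 = touch-down signal)
// 20..25 V of MNs
// 26..27 adaptation traces p of the two sensory INs
// 28..33 muscle activations a
// 34..36 joint angles alpha, beta, gamma
static const int S_VC = 0, S_H = 6, S_VIN = 12, S_VSN = 18, S_VMN = 20,
                 S_P = 26, S_A = 28, S_ANG = 34;
static const int NSL = 37;
static const int NSTATE = NLEG * NSL; // 111

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Pars {
  const double* P;
  double out(double V) const { return sig((V - P[14]) / P[15]); }
  double minf(double V) const { return sig((V - P[5]) / P[6]); }
  double hinf(double V) const { return sig(-(V - P[7]) / P[8]); }
  double tauh(double V) const { return P[9] / std::cosh((V - P[40]) / (2.0 * P[10])); }
};

// angle ranges (degrees): alpha 28-128, beta 30-60, gamma 45-110
static const double ANG_LO[3] = {28.0, 30.0, 45.0};
static const double ANG_HI[3] = {128.0, 60.0, 110.0};

// effective angular velocity honouring the range clamps
static inline double ang_vel(double ang, double v, int k) {
  if (ang <= ANG_LO[k] && v < 0) return 0.0;
  if (ang >= ANG_HI[k] && v > 0) return 0.0;
  return v;
}

static void rhs(const double* x, const double* P, const int* gs, const int* gf,
                double* dx) {
  Pars pp{P};
  const double gL = P[1], EL = P[2], gPc = P[3], EP = P[4], Cc = P[0];
  const double Cp = P[11], gLp = P[12], ELp = P[13];
  const double Einh = P[16], Eexc = P[17];
  const double gcc = P[18], gcpgin = P[19], gtone = P[20], ginmn = P[21],
               gMN = P[22], tact = P[23];
  const double gains[3] = {P[24], P[25], P[26]};
  const double taup = P[27], gsn = P[28];
  const double gsnl_l = P[29], gsnl_d = P[30], gsnt_d = P[31], gsnt_l = P[32];
  const double ggate = P[33];

  for (int l = 0; l < NLEG; ++l) {
    const int b = l * NSL;
    const double* pl = P + NGLOB + l * NPL;

    // CPG neurons
    for (int j = 0; j < 6; ++j) {
      const double V = x[b + S_VC + j], h = x[b + S_H + j];
      const int jp = j ^ 1; // half-center partner
      double I = gL * (V - EL) + gPc * pp.minf(V) * h * (V - EP);
      I += gcc * pp.out(x[b + S_VC + jp]) * (V - Einh);
      I += pl[P_GAPPE + j] * (V - Eexc) + pl[P_GAPPI + j] * (V - Einh);
      if (j < 2) { // protractor-retractor pair, stance gate
        const double g_on = (j == 1) ? (double)gs[l] : 1.0 - (double)gs[l];
        I += ggate * g_on * (V - Eexc);
      } else if (j >= 4) { // extensor-flexor pair, flexion gate
        double gfe = (double)gf[l];
        if (pl[P_EFINV] > 0.5) gfe = 1.0 - gfe;
        const double g_on = (j == 5) ? gfe : 1.0 - gfe;
        I += ggate * g_on * (V - Eexc);
      } else { // levator-depressor pair: phasic position sense
        const double s_lift = pp.out(x[b + S_VSN + 0]);
        const double s_td = pp.out(x[b + S_VSN + 1]);
        if (j == 2) {
          I += gsnl_l * s_lift * (V - Eexc) + gsnt_l * s_td * (V - Einh);
        } else {
          I += gsnt_d * s_td * (V - Eexc) + gsnl_d * s_lift * (V - Einh);
        }
        // intersegmental inhibition of the anterior levator neuron
        if (j == 2 && l < 2) {
          const int bp = (l + 1) * NSL;
          const double bpost = x[bp + S_ANG + 1];
          double w;
          if (pl[P_ISFIX] > 0.5) {
            w = pl[P_ISG];
          } else {
            w = pl[P_ISG] * sig((bpost - pl[P_ISTH]) / pl[P_ISSL]);
            if (pl[P_ISDG] > 0.5) {
              const double dbp = ang_vel(
                  bpost, gains[1] * (x[bp + S_A + 2] - x[bp + S_A + 3]), 1);
              w *= sig(dbp / 0.01);
            }
          }
          I += w * (V - pl[P_ISE]);
        }
      }
      dx[b + S_VC + j] = -I / Cc;
      dx[b + S_H + j] = (pp.hinf(V) - h) / pp.tauh(V);
    }

    // premotor INs: tonically driven, inhibited centrally and by their CPG neuron
    for (int j = 0; j < 6; ++j) {
      const double V = x[b + S_VIN + j];
      double I = gLp * (V - ELp) + gtone * (V - Eexc) + pl[P_GD + j] * (V - Einh);
      I += gcpgin * pp.out(x[b + S_VC + j]) * (V - Einh);
      dx[b + S_VIN + j] = -I / Cp;
    }

    // sensory INs driven by their adaptation trace
    for (int j = 0; j < 2; ++j) {
      const double V = x[b + S_VSN + j];
      double I = gLp * (V - ELp) + gsn * x[b + S_P + j] * (V - Eexc);
      dx[b + S_VSN + j] = -I / Cp;
      dx[b + S_P + j] = -x[b + S_P + j] / taup;
    }

    // motoneurons: uniform excitatory drive, gated by premotor inhibition
    for (int j = 0; j < 6; ++j) {
      const double V = x[b + S_VMN + j];
      double I = gLp * (V - ELp) + gMN * (V - Eexc);
      I += ginmn * pp.out(x[b + S_VIN + j]) * (V - Einh);
      dx[b + S_VMN + j] = -I / Cp;
    }

    // muscle activations follow MN output
    for (int j = 0; j < 6; ++j)
      dx[b + S_A + j] = (pp.out(x[b + S_VMN + j]) - x[b + S_A + j]) / tact;

    // joint angles: antagonistic velocity drive with range clamps
    const double* a = x + b + S_A;
    const double v[3] = {gains[0] * (a[1] - a[0]), gains[1] * (a[2] - a[3]),
                         gains[2] * (a[5] - a[4])};
    for (int k = 0; k < 3; ++k)
      dx[b + S_ANG + k] = ang_vel(x[b + S_ANG + k], v[k], k);
  }
}

static std::string unit_name(int idx) {
  const int l = idx / NSL, o = idx % NSL;
  static const char* legs[3] = {"FL", "ML", "HL"};
  char buf[64];
  if (o < 6) snprintf(buf, sizeof(buf), "%s CPG neuron C%d", legs[l], 6 * l + o + 1);
  else if (o < 12) snprintf(buf, sizeof(buf), "%s CPG h C%d", legs[l], 6 * l + o - 5);
  else if (o < 18) snprintf(buf, sizeof(buf), "%s premotor IN %d", legs[l], o - 11);
  else if (o < 20) snprintf(buf, sizeof(buf), "%s sensory IN %d", legs[l], o - 17);
  else if (o < 26) snprintf(buf, sizeof(buf), "%s MN %d", legs[l], o - 19);
  else snprintf(buf, sizeof(buf), "%s state %d", legs[l], o);
  return std::string(buf);
}

// [[Rcpp::export]]
CharacterVector sw_param_layout() {
  CharacterVector nm(NPAR);
  for (int i = 0; i < NGLOB; ++i) nm[i] = kGlobalNames[i];
  static const char* legs[3] = {"FL", "ML", "HL"};
  static const char* mus[6] = {"1", "2", "3", "4", "5", "6"};
  int k = NGLOB;
  for (int l = 0; l < NLEG; ++l) {
    for (int j = 0; j < 6; ++j) nm[k++] = std::string("gappE") + mus[j] + "." + legs[l];
    for (int j = 0; j < 6; ++j) nm[k++] = std::string("gappI") + mus[j] + "." + legs[l];
    for (int j = 0; j < 6; ++j) nm[k++] = std::string("gd") + mus[j] + "." + legs[l];
    nm[k++] = std::string("is_g.") + legs[l];
    nm[k++] = std::string("is_theta.") + legs[l];
    nm[k++] = std::string("is_slope.") + legs[l];
    nm[k++] = std::string("is_E.") + legs[l];
    nm[k++] = std::string("is_fix.") + legs[l];
    nm[k++] = std::string("is_dgate.") + legs[l];
    nm[k++] = std::string("ef_inv.") + legs[l];
  }
  return nm;
}

// [[Rcpp::export]]
List sw_state_layout() {
  CharacterVector nm(NSTATE);
  static const char* legs[3] = {"FL", "ML", "HL"};
  static const char* ang[3] = {"alpha", "beta", "gamma"};
  for (int l = 0; l < NLEG; ++l) {
    const int b = l * NSL;
    for (int j = 0; j < 6; ++j) {
      nm[b + S_VC + j] = std::string("V.C") + std::to_string(6 * l + j + 1);
      nm[b + S_H + j] = std::string("h.C") + std::to_string(6 * l + j + 1);
      nm[b + S_VIN + j] = std::string("V.IN") + std::to_string(j + 1) + "." + legs[l];
      nm[b + S_VMN + j] = std::string("V.MN") + std::to_string(j + 1) + "." + legs[l];
      nm[b + S_A + j] = std::string("a") + std::to_string(j + 1) + "." + legs[l];
    }
    for (int j = 0; j < 2; ++j) {
      nm[b + S_VSN + j] = std::string("V.SN") + std::to_string(j + 1) + "." + legs[l];
      nm[b + S_P + j] = std::string("p") + std::to_string(j + 1) + "." + legs[l];
    }
    for (int k = 0; k < 3; ++k)
      nm[b + S_ANG + k] = std::string(ang[k]) + "." + legs[l];
  }
  return List::create(_["names"] = nm, _["n"] = NSTATE);
}

// [[Rcpp::export]]
List sw_simulate(NumericVector P0, NumericVector x0, IntegerVector gs0,
                 IntegerVector gf0, double t0, double t_end, double dt,
                 double sample_dt, NumericVector ev_t, IntegerVector ev_idx,
                 NumericVector ev_val) {
  if (P0.size() != NPAR) stop("parameter vector has wrong length");
  if (x0.size() != NSTATE) stop("state vector has wrong length");
  if (dt <= 0) stop("dt must be positive");

  std::vector<double> P(P0.begin(), P0.end());
  std::vector<double> x(x0.begin(), x0.end());
  int gs[NLEG], gf[NLEG];
  for (int l = 0; l < NLEG; ++l) { gs[l] = gs0[l]; gf[l] = gf0[l]; }

  const long nstep = (long)std::llround((t_end - t0) / dt);
  const long sev = std::max(1L, (long)std::llround(sample_dt / dt));
  const long nsamp = nstep / sev + 1;

  NumericMatrix out(nsamp, 1 + NSTATE);
  std::vector<double> k1(NSTATE), k2(NSTATE), k3(NSTATE), k4(NSTATE),
      xt(NSTATE);

  long iev = 0;
  const long nev = ev_t.size();
  long irow = 0;
  Pars pp{P.data()};
  const double Vlim = P[39];

  auto record = [&](double t) {
    out(irow, 0) = t;
    for (int i = 0; i < NSTATE; ++i) out(irow, 1 + i) = x[i];
    ++irow;
  };
  record(t0);

  for (long istep = 0; istep < nstep; ++istep) {
    const double t = t0 + istep * dt;
    // apply scheduled parameter rewrites (events sorted by time)
    while (iev < nev && ev_t[iev] <= t + 1e-9) {
      const int pi = ev_idx[iev];
      if (pi < 0 || pi >= NPAR) stop("event parameter index out of range");
      P[pi] = ev_val[iev];
      ++iev;
    }

    const double pb[3] = {x[0 * NSL + S_ANG + 1], x[1 * NSL + S_ANG + 1],
                          x[2 * NSL + S_ANG + 1]};
    const double pa[3] = {x[0 * NSL + S_ANG + 0], x[1 * NSL + S_ANG + 0],
                          x[2 * NSL + S_ANG + 0]};

    rhs(x.data(), P.data(), gs, gf, k1.data());
    for (int i = 0; i < NSTATE; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    rhs(xt.data(), P.data(), gs, gf, k2.data());
    for (int i = 0; i < NSTATE; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    rhs(xt.data(), P.data(), gs, gf, k3.data());
    for (int i = 0; i < NSTATE; ++i) xt[i] = x[i] + dt * k3[i];
    rhs(xt.data(), P.data(), gs, gf, k4.data());
    for (int i = 0; i < NSTATE; ++i)
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // clamp angles, bound h
    for (int l = 0; l < NLEG; ++l) {
      const int b = l * NSL;
      for (int k = 0; k < 3; ++k) {
        double& ang = x[b + S_ANG + k];
        if (ang < ANG_LO[k]) ang = ANG_LO[k];
        if (ang > ANG_HI[k]) ang = ANG_HI[k];
      }
      for (int j = 0; j < 6; ++j) {
        double& h = x[b + S_H + j];
        if (h < 0) h = 0;
        if (h > 1) h = 1;
      }
    }

    // sanity check on membrane potentials
    for (int l = 0; l < NLEG; ++l) {
      const int b = l * NSL;
      for (int o = 0; o < 26; ++o) {
        if (o >= 6 && o < 12) continue;
        const double V = x[b + o];
        if (!std::isfinite(V) || std::fabs(V) > Vlim)
          stop("numerical blow-up in %s at t = %.3f ms",
               unit_name(b + o).c_str(), t + dt);
      }
    }

    // discrete latches: Schmitt triggers on beta with directional debounce
    const double th_pr = P[34], th_ef = P[35], hy = P[36];
    const double a_pro = P[37], a_ret = P[38];
    for (int l = 0; l < NLEG; ++l) {
      const int b = l * NSL;
      const double bnow = x[b + S_ANG + 1], bprev = pb[l];
      const double anow = x[b + S_ANG + 0], aprev = pa[l];
      if (gs[l] == 0 && bnow <= th_pr && bnow < bprev) gs[l] = 1;
      else if (gs[l] == 1 && bnow >= th_pr + hy && bnow > bprev) gs[l] = 0;
      if (gf[l] == 0 && bnow <= th_ef && bnow < bprev) gf[l] = 1;
      else if (gf[l] == 1 && bnow >= th_pr + hy && bnow > bprev) gf[l] = 0;
      // phasic position-sense triggers
      if (gs[l] == 1 && aprev < a_ret && anow >= a_ret) x[b + S_P + 0] = 1.0;
      if (gs[l] == 0 && aprev > a_pro && anow <= a_pro) x[b + S_P + 1] = 1.0;
    }

    if ((istep + 1) % sev == 0 && irow < nsamp) record(t0 + (istep + 1) * dt);
  }

  (void)pp;
  return List::create(
      _["out"] = out, _["state"] = NumericVector(x.begin(), x.end()),
      _["gs"] = IntegerVector(gs, gs + NLEG),
      _["gf"] = IntegerVector(gf, gf + NLEG),
      _["P"] = NumericVector(P.begin(), P.end()));
}
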