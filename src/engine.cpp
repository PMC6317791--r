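// Closed-loop CRT circuit engine.
//
// One call simulates a full trial: stimulus bump -> Poisson afferent spikes ->
// network step (six Izhikevich populations, SD conductances, T-type calcium,
// dSTP) -> motor error map readout -> gaze update.  All arithmetic follows the
// same expression order as the pure-R reference step so the two paths agree
// spike-for-spike; sums accumulate sequentially in double precision, matching a plain R loop.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct SdChannel {
  std::vector<double> Q, g, tr, tf, coef;
  std::vector<int> pulse;
  int n;
  void init(const List& spec) {
    NumericVector trv = spec["tau_rise"], tfv = spec["tau_fall"], cv = spec["coef"];
    n = trv.size();
    tr.assign(trv.begin(), trv.end());
    tf.assign(tfv.begin(), tfv.end());
    coef.assign(cv.begin(), cv.end());
    Q.assign(n, 0.0); g.assign(n, 0.0); pulse.assign(n, 0);
  }
  // advance one Euler step; spikes from the previous step load the K pulse
  void step(const std::vector<int>& spikes, double h, double kmag, int kdur) {
    for (int i = 0; i < n; ++i) {
      if (spikes[i]) pulse[i] = kdur;
      double K = pulse[i] > 0 ? kmag : 0.0;
      if (pulse[i] > 0) pulse[i]--;
      Q[i] += h * ((1.0 - Q[i]) * K - Q[i] / tr[i]);
      g[i] += h * (coef[i] * (1.0 - g[i]) * Q[i] - g[i] / tf[i]);
      // flush decaying tails to zero before they reach subnormal range
      if (Q[i] < 1e-30) Q[i] = 0.0;
      if (g[i] < 1e-30) g[i] = 0.0;
    }
  }
};

struct Pop {
  std::vector<double> a, b, c, d, v, u;
  std::vector<int> sp;
  double thresh;
  int n;
  void init(const List& spec) {
    NumericVector av = spec["a"], bv = spec["b"], cv = spec["c"], dv = spec["d"],
                  v0 = spec["v0"];
    thresh = as<double>(spec["spike_threshold"]);
    n = av.size();
    a.assign(av.begin(), av.end()); b.assign(bv.begin(), bv.end());
    c.assign(cv.begin(), cv.end()); d.assign(dv.begin(), dv.end());
    v.assign(v0.begin(), v0.end());
    u.resize(n);
    for (int i = 0; i < n; ++i) u[i] = b[i] * v[i];
    sp.assign(n, 0);
  }
  void step(const std::vector<double>& I, double h) {
    for (int i = 0; i < n; ++i) {
      double vi = v[i], ui = u[i];
      double vn = vi + h * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
      double un = ui + h * (a[i] * (b[i] * vi - ui));
      if (vn >= thresh) { sp[i] = 1; vn = c[i]; un = un + d[i]; } else sp[i] = 0;
      v[i] = vn; u[i] = un;
    }
  }
};

// steady-state and time-constant curves of the T-type calcium gates
inline double m_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 79.0) / 6.2)); }
inline double h_inf(double v) { return 1.0 / (1.0 + std::exp((v + 92.0) / 4.0)); }
inline double tau_m(double v) {
  return 0.999 + 0.333 / (std::exp((v + 31.0) / 10.0) + std::exp(-(v + 106.0) / 15.0));
}
inline double tau_h(double v) {
  return (30.8 + (211.4 + std::exp((v + 119.2) / 5.0)) /
                     (1.0 + std::exp((v + 90.0) / 3.2))) / 3.7373;
}

const double kFaraday = 96485.3, kGas = 8.314, kTempK = 298.0;
const double kZCa = 2.0, kPCa = 30.0, kCaExt = 2.0, kCaRest = 0.00024;

// Goldman-Hodgkin-Katz flux; v in mV, linear limit at v = 0
inline double ghk_flux(double v, double ca_int) {
  double V = v / 1000.0;
  double x = kZCa * kFaraday * V / (kGas * kTempK);
  if (std::fabs(x) < 1e-6) return kPCa * kZCa * kFaraday * (ca_int - kCaExt);
  double num = ca_int - kCaExt * std::exp(-x);
  double den = 1.0 - std::exp(-x);
  return kPCa * kZCa * kZCa * kFaraday * kFaraday * V / (kGas * kTempK) * num / den;
}

struct TChannel {
  std::vector<double> m, h, ca, raw;
  double amp, kappa;
  int n;
  void init(int n_, double amp_, double kappa_, double v0) {
    n = n_; amp = amp_; kappa = kappa_;
    m.assign(n, m_inf(v0)); h.assign(n, h_inf(v0));
    ca.assign(n, kCaRest); raw.assign(n, 0.0);
  }
  // depolarizing model current from the previous-step state
  void current(const std::vector<double>& v, std::vector<double>& out) {
    for (int i = 0; i < n; ++i) {
      raw[i] = amp * m[i] * m[i] * h[i] * ghk_flux(v[i], ca[i]);
      out[i] = -kappa * raw[i];
    }
  }
  void advance(const std::vector<double>& v, double hstep) {
    for (int i = 0; i < n; ++i) {
      double rect = raw[i] > 0.0 ? raw[i] : 0.0;
      ca[i] += hstep * (-10.0 / (kZCa * kFaraday) * rect - 0.2 * (ca[i] - kCaRest));
      m[i] += hstep * (m_inf(v[i]) - m[i]) / tau_m(v[i]);
      h[i] += hstep * (h_inf(v[i]) - h[i]) / tau_h(v[i]);
    }
  }
};

struct Mat {
  const double* p; int npre, npost;
  void init(const NumericMatrix& m) { p = &m[0]; npre = m.nrow(); npost = m.ncol(); }
  double colsum(const std::vector<double>& g, int post) const {
    const double* col = p + (size_t)post * npre;
    double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
    int i = 0;
    for (; i + 4 <= npre; i += 4) {
      a0 += col[i] * g[i];
      a1 += col[i + 1] * g[i + 1];
      a2 += col[i + 2] * g[i + 2];
      a3 += col[i + 3] * g[i + 3];
    }
    double acc = (a0 + a1) + (a2 + a3);
    for (; i < npre; ++i) acc += col[i] * g[i];
    return acc;
  }
};

inline double nmda_gate(double v) {
  return 1.0 / (1.0 + 0.4202 * std::exp(-0.062 * v));
}

} // namespace

// [[Rcpp::export]]
List crt_engine(List par) {
  const double h = as<double>(par["step_h"]);
  const int n_steps = as<int>(par["n_steps"]);
  const int stride = as<int>(par["record_stride"]);
  const double kmag = as<double>(par["spike_pulse_magnitude"]);
  const int kdur = as<int>(par["spike_pulse_steps"]);

  List pops = par["pops"];
  Pop T, R, M, D, PV, CB;
  T.init(pops["T"]); R.init(pops["R"]); M.init(pops["M"]);
  D.init(pops["D"]); PV.init(pops["PV"]); CB.init(pops["CB"]);
  const int NT = T.n, NR = R.n, NM = M.n, ND = D.n, NPV = PV.n, NCB = CB.n;

  List syn = par["synapses"];
  SdChannel s_extf, s_extn, s_t, s_rb, s_mf, s_mn, s_df, s_dx, s_pv, s_cb;
  s_extf.init(syn["ext_fast"]); s_extn.init(syn["ext_nmda"]);
  s_t.init(syn["t_fast"]);      s_rb.init(syn["r_gabab"]);
  s_mf.init(syn["m_fast"]);     s_mn.init(syn["m_nmda"]);
  s_df.init(syn["d_fast"]);     s_dx.init(syn["d_xslow"]);
  s_pv.init(syn["pv_fast"]);    s_cb.init(syn["cb_fast"]);

  List tch = par["t_channels"];
  List tchT = tch["T"], tchR = tch["R"];
  TChannel tT, tR;
  tT.init(NT, as<double>(tchT["amplitude"]), as<double>(tchT["unit_scale"]),
          as<double>(tchT["v_init"]));
  tR.init(NR, as<double>(tchR["amplitude"]), as<double>(tchR["unit_scale"]),
          as<double>(tchR["v_init"]));

  List wl = par["weights"];
  NumericMatrix mWdt = wl["dt"], mWtmp = wl["tmp"], mWtmd = wl["tmd"],
      mWmd = wl["md"], mWtr = wl["tr"], mWdr = wl["dr"], mWgap = wl["gap"],
      mWpvpv = wl["pvpv"], mWpvm = wl["pvm"], mWcbm = wl["cbm"],
      mWmpv = wl["mpv"], mWmcb = wl["mcb"];
  Mat Wdt, Wtmp, Wtmd, Wmd, Wtr, Wdr, Wgap, Wpvpv, Wpvm, Wcbm, Wmpv, Wmcb;
  Wdt.init(mWdt); Wtmp.init(mWtmp); Wtmd.init(mWtmd); Wmd.init(mWmd);
  Wtr.init(mWtr); Wdr.init(mWdr); Wgap.init(mWgap); Wpvpv.init(mWpvpv);
  Wpvm.init(mWpvm); Wcbm.init(mWcbm); Wmpv.init(mWmpv); Wmcb.init(mWmcb);

  List amp = par["amplitudes"];
  const double A_dt = amp["dt"], A_tmp = amp["tmp"], A_tmd = amp["tmd"],
      A_md = amp["md"], A_tr = amp["tr"], A_dr = amp["dr"], A_gap = amp["gap"],
      A_pvpv = amp["pvpv"], A_pvm = amp["pvm"], A_cbm = amp["cbm"],
      A_mpv_a = amp["mpv_ampa"], A_mpv_n = amp["mpv_nmda"],
      A_mcb_a = amp["mcb_ampa"], A_mcb_n = amp["mcb_nmda"],
      A_rt = amp["rt"], A_stp = amp["astp"],
      A_ext_a = amp["ext_ampa"], A_ext_n = amp["ext_nmda"];

  NumericVector WLv = par["motor_left"], WRv = par["motor_right"];

  List task = par["task"];
  NumericVector xTv = task["target"];          // per step
  NumericVector xDv = task["distractor"];      // per step, NA when absent
  const double rate_base = task["rate_base"], rate_amp = task["rate_amp"],
      rate_max = task["rate_max"], bump_p = task["bump_exponent"];
  double xc = as<double>(task["gaze_init"]);
  const double gaze_lo = task["gaze_lo"], gaze_hi = task["gaze_hi"];

  List pert = par["perturbation"];
  const int on_step = as<int>(pert["onset_step"]), off_step = as<int>(pert["offset_step"]);
  const double f_pvn = pert["pv_nmda"], f_cbn = pert["cb_nmda"],
      f_stp = pert["dstp"], f_pvg = pert["pv_gaba"], f_cbg = pert["cb_gaba"],
      ihyp = pert["i_hyp"];

  const bool use_poisson = as<bool>(par["use_poisson"]);
  LogicalMatrix ext_given(1, 1);
  if (!use_poisson) ext_given = as<LogicalMatrix>(par["ext_spikes"]);

  const int n_rec = (n_steps + stride - 1) / stride;
  NumericVector rec_eye(n_rec), rec_tgt(n_rec), rec_dis(n_rec), rec_mln(n_rec);
  NumericMatrix rec_pt(NT, n_rec);
  std::vector<int> rast_step, rast_neuron, rast_pop;

  std::vector<double> IT(NT), IR(NR), IM(NM), ID(ND), IPV(NPV), ICB(NCB);
  std::vector<double> tTI(NT), tRI(NR), PT(NT), gx6(ND);
  std::vector<int> ext_sp(NT, 0);

  GetRNGstate();
  for (int n = 0; n < n_steps; ++n) {
    const bool pert_on = (n >= on_step && n < off_step);
    const double fpvn = pert_on ? f_pvn : 1.0, fcbn = pert_on ? f_cbn : 1.0,
        fstp = pert_on ? f_stp : 1.0, fpvg = pert_on ? f_pvg : 1.0,
        fcbg = pert_on ? f_cbg : 1.0, ih = pert_on ? ihyp : 0.0;

    // external input: stimulus (and distractor) bump over the afferent field
    const double xT = xTv[n], xD = xDv[n];
    if (use_poisson) {
      for (int i = 0; i < NT; ++i) {
        double u1 = 0.5 * NT - (i + 1.0) - (xc - xT);
        double rate = rate_base + rate_amp * std::exp(-std::pow(std::fabs(u1), bump_p) / 2.0);
        if (!ISNAN(xD)) {
          double u2 = 0.5 * NT - (i + 1.0) - (xc - xD);
          double r2 = rate_base + rate_amp * std::exp(-std::pow(std::fabs(u2), bump_p) / 2.0);
          if (r2 > rate) rate = r2;
        }
        if (rate > rate_max) rate = rate_max;
        ext_sp[i] = unif_rand() < rate * h / 1000.0 ? 1 : 0;
      }
    } else {
      for (int i = 0; i < NT; ++i) ext_sp[i] = ext_given(n, i) ? 1 : 0;
    }

    // dSTP factor and all input currents from previous-step states
    for (int j = 0; j < ND; ++j) {
      double g = s_dx.g[j];
      double g2 = g * g; gx6[j] = g2 * g2 * g2;
    }
    {
      double accg = 0.0;
      for (int j = 0; j < NR; ++j) accg += s_rb.g[j];
      double sum_rb = (double)accg;
      tT.current(T.v, tTI);
      for (int i = 0; i < NT; ++i) {
        PT[i] = 1.0 / (1.0 + A_stp * fstp * A_dt * Wdt.colsum(gx6, i));
        IT[i] = (0.0 - T.v[i]) * (A_ext_a * s_extf.g[i] + A_dt * Wdt.colsum(s_df.g, i)) +
                (0.0 - T.v[i]) * nmda_gate(T.v[i]) * A_ext_n * s_extn.g[i] +
                tTI[i] + PT[i] * (-90.0 - T.v[i]) * A_rt * sum_rb;
      }
    }
    tR.current(R.v, tRI);
    for (int i = 0; i < NR; ++i) {
      double accg = 0.0;
      const double* col = Wgap.p + (size_t)i * NR;
      for (int j = 0; j < NR; ++j) accg += col[j] * (R.v[j] - R.v[i]);
      IR[i] = (0.0 - R.v[i]) * (A_tr * Wtr.colsum(s_t.g, i) + A_dr * Wdr.colsum(s_df.g, i)) +
              tRI[i] + A_gap * (double)accg + ih;
    }
    for (int i = 0; i < NM; ++i) {
      double dist = A_tmd * Wtmd.colsum(s_t.g, i) - fcbg * A_cbm * Wcbm.colsum(s_cb.g, i);
      if (dist < 0.0) dist = 0.0;
      IM[i] = (0.0 - M.v[i]) * (A_tmp * Wtmp.colsum(s_t.g, i) + dist) +
              (-70.0 - M.v[i]) * fpvg * A_pvm * Wpvm.colsum(s_pv.g, i);
    }
    for (int i = 0; i < NPV; ++i) {
      IPV[i] = (0.0 - PV.v[i]) * A_mpv_a * Wmpv.colsum(s_mf.g, i) +
               (0.0 - PV.v[i]) * nmda_gate(PV.v[i]) * fpvn * A_mpv_n * Wmpv.colsum(s_mn.g, i) +
               (-70.0 - PV.v[i]) * fpvg * A_pvpv * Wpvpv.colsum(s_pv.g, i);
    }
    for (int i = 0; i < NCB; ++i) {
      ICB[i] = (0.0 - CB.v[i]) * A_mcb_a * Wmcb.colsum(s_mf.g, i) +
               (0.0 - CB.v[i]) * nmda_gate(CB.v[i]) * fcbn * A_mcb_n * Wmcb.colsum(s_mn.g, i);
    }
    for (int i = 0; i < ND; ++i)
      ID[i] = (0.0 - D.v[i]) * A_md * Wmd.colsum(s_mf.g, i);

    // record the state as of this step
    if (n % stride == 0) {
      int k = n / stride;
      double accv = 0.0;
      for (int i = 0; i < NM; ++i) accv += M.v[i];
      rec_eye[k] = xc; rec_tgt[k] = xT; rec_dis[k] = xD;
      rec_mln[k] = (double)accv;
      for (int i = 0; i < NT; ++i) rec_pt(i, k) = PT[i];
    }

    // conductances, gates, calcium
    s_extf.step(ext_sp, h, kmag, kdur); s_extn.step(ext_sp, h, kmag, kdur);
    s_t.step(T.sp, h, kmag, kdur);      s_rb.step(R.sp, h, kmag, kdur);
    s_mf.step(M.sp, h, kmag, kdur);     s_mn.step(M.sp, h, kmag, kdur);
    s_df.step(D.sp, h, kmag, kdur);     s_dx.step(D.sp, h, kmag, kdur);
    s_pv.step(PV.sp, h, kmag, kdur);    s_cb.step(CB.sp, h, kmag, kdur);
    tT.advance(T.v, h); tR.advance(R.v, h);

    // motor error map readout and gaze update
    {
      double accL = 0.0, accR = 0.0;
      for (int i = 0; i < NM; ++i) accL += WLv[i] * s_mf.g[i];
      for (int i = 0; i < NM; ++i) accR += WRv[i] * s_mf.g[i];
      xc = xc + ((double)accR - (double)accL);
      if (xc < gaze_lo) xc = gaze_lo;
      if (xc > gaze_hi) xc = gaze_hi;
    }

    // membrane update, spike detection and reset
    T.step(IT, h); R.step(IR, h); M.step(IM, h);
    D.step(ID, h); PV.step(IPV, h); CB.step(ICB, h);

    Pop* ps[6] = {&T, &R, &M, &D, &PV, &CB};
    for (int p = 0; p < 6; ++p) {
      const Pop& pp = *ps[p];
      for (int i = 0; i < pp.n; ++i) if (pp.sp[i]) {
        rast_step.push_back(n); rast_neuron.push_back(i + 1); rast_pop.push_back(p);
      }
    }
  }
  PutRNGstate();

  return List::create(
      _["eye"] = rec_eye, _["target"] = rec_tgt, _["distractor"] = rec_dis,
      _["mln_sum"] = rec_mln, _["p_t"] = rec_pt,
      _["raster_step"] = IntegerVector(rast_step.begin(), rast_step.end()),
      _["raster_neuron"] = IntegerVector(rast_neuron.begin(), rast_neuron.end()),
      _["raster_pop"] = IntegerVector(rast_pop.begin(), rast_pop.end()));
}
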