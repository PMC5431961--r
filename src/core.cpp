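#include <Rcpp.h>
using namespace Rcpp;

// Second-order synaptic kernel H(s) = W/(s + 1/tau)^2, advanced with the
// exact matrix exponential under a zero-order hold on the input.  The state
// transition for the double pole at -1/tau is
//   Phi = e^{-dt/tau} [ 1 + dt/tau        dt        ]
//                     [ -dt/tau^2     1 - dt/tau    ]
// and the particular solution for constant input x is (W tau^2 x, 0).
struct KernelProp {
  double p11, p12, p21, p22, gain; // gain = W * tau^2
  void init(double W, double tau, double dt) {
    double e = std::exp(-dt / tau);
    p11 = e * (1.0 + dt / tau);
    p12 = e * dt;
    p21 = -e * dt / (tau * tau);
    p22 = e * (1.0 - dt / tau);
    gain = W * tau * tau;
  }
  inline void step(double &y, double &yd, double x) const {
    double ys = gain * x;
    double ny  = p11 * (y - ys) + p12 * yd + ys;
    double nyd = p21 * (y - ys) + p22 * yd;
    y = ny; yd = nyd;
  }
};

static inline double sigm(double v, double e0, double v0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// Three-subpopulation neural mass model (granule-cell analog with recurrent
// excitation, slow dendritic and fast somatic GABAergic feedback, slow->fast
// interneuron inhibition).  States: five kernel instances (y, ydot) each.
//   y0: GC output PSP (excitatory kernel, drives interneurons)
//   y1: excitatory input PSP at GC (noise + recurrent collaterals)
//   y2: slow dendritic IPSP at GC
//   y3: fast somatic IPSP at GC
//   y4: slow IPSP at fast interneurons
// LFP = y1 - y2 - y3 (net summed PSP at the GC population).
// [[Rcpp::export]]
List simulate_nmm_cpp(int n, double dt,
                      double A, double B, double G,
                      double tau_a, double tau_b, double tau_g,
                      NumericVector C,      // C1..C7
                      double e0, double v0, double r,
                      double noise_mean, double noise_sd,
                      NumericVector modulation, // length n or 0
                      NumericVector dv1, NumericVector dv2, NumericVector dv3,
                      bool return_states) {
  KernelProp ke, ks, kf;
  ke.init(A / tau_a, tau_a, dt);  // W = A * a, tau = 1/a  => W = A/tau
  ks.init(B / tau_b, tau_b, dt);
  kf.init(G / tau_g, tau_g, dt);

  const bool has_mod = modulation.size() == n;
  const bool has_dv1 = dv1.size() == n, has_dv2 = dv2.size() == n,
             has_dv3 = dv3.size() == n;
  double y0 = 0, y0d = 0, y1 = 0, y1d = 0, y2 = 0, y2d = 0,
         y3 = 0, y3d = 0, y4 = 0, y4d = 0;
  NumericVector lfp(n);
  NumericMatrix states;
  if (return_states) states = NumericMatrix(n, 5);

  for (int t = 0; t < n; ++t) {
    double d1 = has_dv1 ? dv1[t] : 0.0;
    double d2 = has_dv2 ? dv2[t] : 0.0;
    double d3 = has_dv3 ? dv3[t] : 0.0;
    double p = noise_mean + noise_sd * R::norm_rand();
    if (has_mod) p += modulation[t];

    double v_gc  = y1 - y2 - y3 + d1;            // summed PSP at GC
    double v_fsi = C[4] * y0 - C[5] * y4 + d2;   // input to fast interneurons
    double v_sdi = C[2] * y0 + d3;               // input to slow interneurons

    double x0 = sigm(v_gc, e0, v0, r);                 // GC firing rate
    double x1 = p + C[1] * sigm(C[0] * y0, e0, v0, r); // excitatory drive
    double x2 = C[3] * sigm(v_sdi, e0, v0, r);         // slow IPSP drive
    double x3 = C[6] * sigm(v_fsi, e0, v0, r);         // fast IPSP drive
    double x4 = sigm(v_sdi, e0, v0, r);                // slow -> fast pathway

    ke.step(y0, y0d, x0);
    ke.step(y1, y1d, x1);
    ks.step(y2, y2d, x2);
    kf.step(y3, y3d, x3);
    ks.step(y4, y4d, x4);

    lfp[t] = y1 - y2 - y3;
    if (!std::isfinite(lfp[t]))
      stop("non-finite model state at t = %f s; check parameters", t * dt);
    if (return_states) {
      states(t, 0) = y0; states(t, 1) = y1; states(t, 2) = y2;
      states(t, 3) = y3; states(t, 4) = y4;
    }
  }
  if (return_states)
    return List::create(_["lfp"] = lfp, _["states"] = states);
  return List::create(_["lfp"] = lfp);
}

// Page-Hinkley change detection on a signal.  Rise statistic
// m_t = sum(x_i - xbar_t - delta) alarms when m_t - min_s m_s >= lambda;
// two-sided adds the mirrored fall statistic with +delta.  The baseline
// xbar_t is either the
// running mean since the last alarm (use_mean0 = false) or a fixed
// reference level mean0 learned from change-free data.  An alarm fires
// when m_t - min_s m_s >= lambda (rise) or, two-sided, when
// max_s m_s - m_t >= lambda (fall).  Statistic and extrema (and the
// running mean, if used) reset after each alarm.  Returns 1-based alarm
// indices.
// [[Rcpp::export]]
IntegerVector page_hinkley_cpp(NumericVector x, double delta, double lambda,
                               bool two_sided, bool use_mean0,
                               double mean0) {
  std::vector<int> alarms;
  // separate rise/fall statistics so the drift term guards both sides
  double mu = 0, mu_min = 0, md = 0, md_max = 0, sum = 0;
  long cnt = 0;
  for (int t = 0; t < x.size(); ++t) {
    double mean;
    if (use_mean0) {
      mean = mean0;
    } else {
      sum += x[t];
      cnt += 1;
      mean = sum / cnt;
    }
    mu += x[t] - mean - delta;
    if (mu < mu_min) mu_min = mu;
    bool alarm = mu - mu_min >= lambda;
    if (two_sided) {
      md += x[t] - mean + delta;
      if (md > md_max) md_max = md;
      alarm = alarm || (md_max - md >= lambda);
    }
    if (alarm) {
      alarms.push_back(t + 1);
      mu = 0; mu_min = 0; md = 0; md_max = 0; sum = 0; cnt = 0;
    }
  }
  return wrap(alarms);
}

// Electrode-electrolyte interface: faradaic impedance Zf in parallel with a
// double-layer capacitance Cdl, in series with the solution resistance Rs.
//   Cdl dVdl/dt = i - Vdl/Zf
// current mode:  i = drive (ideal current source)
// voltage mode:  i = (Vapp - Vdl)/Rs
// Returns the tissue current i(t) and the double-layer voltage Vdl(t).
// [[Rcpp::export]]
List interface_ode_cpp(NumericVector drive, double Zf, double Cdl, double Rs,
                       bool voltage_mode, double dt) {
  int n = drive.size();
  NumericVector i_out(n), vdl_out(n);
  double vdl = 0;
  for (int t = 0; t < n; ++t) {
    double i = voltage_mode ? (drive[t] - vdl) / Rs : drive[t];
    vdl += dt * (i - vdl / Zf) / Cdl;
    i_out[t] = i;
    vdl_out[t] = vdl;
  }
  return List::create(_["current"] = i_out, _["v_dl"] = vdl_out);
}
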