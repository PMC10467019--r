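#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment conductance-based integrator.
// Gates use exponential Euler (exact for frozen V over a step); the membrane
// potential uses forward Euler so that the discrete current balance
// C*(V[k+1]-V[k])/dt = I_inj[k] - sum_c I_c[k] holds exactly per step.

struct Gate {
  bool present;
  double half, slope, tau_base, tau_amp, tau_center, tau_width;
  int p;
  double x; // state

  double xinf(double v) const {
    return 1.0 / (1.0 + std::exp((half - v) / slope));
  }
  double tau(double v) const {
    double z = (v - tau_center) / tau_width;
    return tau_base + tau_amp * std::exp(-z * z);
  }
};

struct Channel {
  double gbar, e_rev;
  Gate act, inact;
};

static Gate parse_gate(List g) {
  Gate out;
  out.present = true;
  out.half = as<double>(g["half"]);
  out.slope = as<double>(g["slope"]);
  out.p = as<int>(g["p"]);
  NumericVector tp = g["tau"]; // base, amp, center, width
  out.tau_base = tp[0];
  out.tau_amp = tp[1];
  out.tau_center = tp[2];
  out.tau_width = tp[3];
  out.x = 0.0;
  return out;
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericVector i_inj, double dt, double cap, double v_init,
                   List channels) {
  int n = i_inj.size();
  int nc = channels.size();
  std::vector<Channel> ch(nc);
  for (int c = 0; c < nc; ++c) {
    List cl = channels[c];
    ch[c].gbar = as<double>(cl["gbar"]);
    ch[c].e_rev = as<double>(cl["e_rev"]);
    ch[c].act.present = false;
    ch[c].inact.present = false;
    if (cl.containsElementNamed("act") && !Rf_isNull(cl["act"]))
      ch[c].act = parse_gate(cl["act"]);
    if (cl.containsElementNamed("inact") && !Rf_isNull(cl["inact"]))
      ch[c].inact = parse_gate(cl["inact"]);
    if (ch[c].act.present) ch[c].act.x = ch[c].act.xinf(v_init);
    if (ch[c].inact.present) ch[c].inact.x = ch[c].inact.xinf(v_init);
  }

  NumericVector V(n);
  NumericMatrix I(n, nc);
  double v = v_init;

  for (int k = 0; k < n; ++k) {
    V[k] = v;
    double itot = 0.0;
    for (int c = 0; c < nc; ++c) {
      double open = 1.0;
      if (ch[c].act.present) {
        double m = ch[c].act.x;
        for (int j = 0; j < ch[c].act.p; ++j) open *= m;
      }
      if (ch[c].inact.present) open *= ch[c].inact.x;
      double ic = ch[c].gbar * open * (v - ch[c].e_rev); // nA; + = outward
      I(k, c) = ic;
      itot += ic;
    }
    // gate update at the pre-step voltage
    for (int c = 0; c < nc; ++c) {
      if (ch[c].act.present) {
        double xi = ch[c].act.xinf(v), tv = ch[c].act.tau(v);
        ch[c].act.x = xi + (ch[c].act.x - xi) * std::exp(-dt / tv);
      }
      if (ch[c].inact.present) {
        double xi = ch[c].inact.xinf(v), tv = ch[c].inact.tau(v);
        ch[c].inact.x = xi + (ch[c].inact.x - xi) * std::exp(-dt / tv);
      }
    }
    v = v + dt * (i_inj[k] - itot) / cap;
    if (!std::isfinite(v) || std::fabs(v) > 200.0)
      stop("integration failure: |V| > 200 mV (V = %.1f) at step %d (t = %.3f ms)",
           v, k + 1, (k + 1) * dt);
  }

  return List::create(_["V"] = V, _["I"] = I);
}
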