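#include <Rcpp.h>
using namespace Rcpp;

// Mitchell-Schaeffer two-variable model with forward parameter sensitivities.
//
// State y = (v, h, sv_out, sh_out, sv_close, sh_close) where sv_out = dv/dtau_out
// etc.  The gate equation switches regime at v = v_gate; the sensitivity ODEs use
// the regime indicated by the nominal v at each Runge-Kutta stage, and when the
// trajectory crosses the gate the sensitivities receive the standard jump
// correction for state-dependent switching,
//   s(t_s+) = s(t_s-) + (f- - f+) dts/dp,   dts/dp = -s_v(t_s) / v'(t_s),
// which only touches the h-components (the v-equation is continuous across the
// switch).  The crossing is located by linear interpolation within the step.

struct MSDeriv {
  double tau_in, tau_out, tau_open, tau_close, v_gate;
  bool with_sens;
  // reciprocals precomputed once per template (divisions dominate the step cost)
  double r_in, r_out, r_open, r_close, r_out2, r_close2;

  inline void init() {
    r_in = 1.0 / tau_in;
    r_out = 1.0 / tau_out;
    r_open = 1.0 / tau_open;
    r_close = 1.0 / tau_close;
    r_out2 = r_out * r_out;
    r_close2 = r_close * r_close;
  }

  inline void operator()(const double *y, double *dy) const {
    const double v = y[0], h = y[1];
    const bool closed = (v >= v_gate);  // v == v_gate assigned to the closing branch
    const double fv = h * v * v * (1.0 - v) * r_in - v * r_out;
    const double fh = closed ? (-h * r_close) : ((1.0 - h) * r_open);
    dy[0] = fv;
    dy[1] = fh;
    if (!with_sens) return;
    // Jacobian entries of the (v,h) system
    const double dfdv = h * (2.0 * v - 3.0 * v * v) * r_in - r_out;
    const double dfdh = v * v * (1.0 - v) * r_in;
    const double dgdh = closed ? (-r_close) : (-r_open);
    // d/dtau_out: df/dtau_out = v / tau_out^2, dg/dtau_out = 0
    dy[2] = dfdv * y[2] + dfdh * y[3] + v * r_out2;
    dy[3] = dgdh * y[3];
    // d/dtau_close: df/dtau_close = 0, dg/dtau_close = h / tau_close^2 (closed only)
    dy[4] = dfdv * y[4] + dfdh * y[5];
    dy[5] = dgdh * y[5] + (closed ? h * r_close2 : 0.0);
  }
};

static void rk4_path(const MSDeriv &f, double v0, double h0, double dt,
                     int n_steps, bool with_sens,
                     double *v, double *h, double *dvdt,
                     double *s_out, double *s_close) {
  const int dim = with_sens ? 6 : 2;
  double y[6] = {v0, h0, 0.0, 0.0, 0.0, 0.0};
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int j = dim; j < 6; ++j) y[j] = 0.0;

  double y_prev[6];

  for (int i = 0; i <= n_steps; ++i) {
    f(y, k1);
    v[i] = y[0];
    h[i] = y[1];
    dvdt[i] = k1[0];
    if (with_sens) { s_out[i] = y[2]; s_close[i] = y[4]; }
    if (i == n_steps) break;
    for (int j = 0; j < dim; ++j) y_prev[j] = y[j];
    for (int j = 0; j < dim; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    f(tmp, k2);
    for (int j = 0; j < dim; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    f(tmp, k3);
    for (int j = 0; j < dim; ++j) tmp[j] = y[j] + dt * k3[j];
    f(tmp, k4);
    for (int j = 0; j < dim; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    if (with_sens) {
      const bool closed_prev = (y_prev[0] >= f.v_gate);
      const bool closed_new = (y[0] >= f.v_gate);
      if (closed_prev != closed_new && y[0] != y_prev[0]) {
        // gate crossing inside the step: apply the sensitivity jump
        const double th = (f.v_gate - y_prev[0]) / (y[0] - y_prev[0]);
        const double h_c = y_prev[1] + th * (y[1] - y_prev[1]);
        const double fv_c = h_c * f.v_gate * f.v_gate * (1.0 - f.v_gate) /
                                f.tau_in - f.v_gate / f.tau_out;
        // h-equation RHS on either side of the switch, at the crossing state
        const double fh_closed = -h_c / f.tau_close;
        const double fh_open = (1.0 - h_c) / f.tau_open;
        const double fh_before = closed_prev ? fh_closed : fh_open;
        const double fh_after = closed_prev ? fh_open : fh_closed;
        if (fv_c != 0.0) {
          for (int p = 0; p < 2; ++p) {   // p = 0: tau_out, p = 1: tau_close
            const int iv = 2 + 2 * p, ih = 3 + 2 * p;
            const double sv_c = y_prev[iv] + th * (y[iv] - y_prev[iv]);
            // g = v - v_gate has no explicit parameter dependence
            const double dts = -sv_c / fv_c;
            y[ih] += (fh_before - fh_after) * dts;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".ms_integrate_cpp")]]
List ms_integrate_cpp(double tau_in, double tau_out, double tau_open,
                      double tau_close, double v_gate,
                      double v0, double h0,
                      double duration, double dt, bool with_sens) {
  const int n_steps = (int)std::ceil(duration / dt - 1e-9);
  const int n = n_steps + 1;
  MSDeriv f{tau_in, tau_out, tau_open, tau_close, v_gate, with_sens};
  f.init();
  NumericVector v(n), h(n), dvdt(n);
  NumericVector s_out(with_sens ? n : 0), s_close(with_sens ? n : 0);
  rk4_path(f, v0, h0, dt, n_steps, with_sens,
           v.begin(), h.begin(), dvdt.begin(),
           with_sens ? s_out.begin() : v.begin(),
           with_sens ? s_close.begin() : v.begin());
  NumericVector time(n);
  for (int i = 0; i < n; ++i) time[i] = i * dt;
  return List::create(_["time"] = time, _["v"] = v, _["h"] = h,
                      _["dv_dt"] = dvdt, _["s_out"] = s_out,
                      _["s_close"] = s_close);
}

// Integrate one template per (tau_out, tau_close) pair; columns of the returned
// matrices are templates on the shared uniform grid 0, dt, ..., n_steps*dt.
// [[Rcpp::export(name = ".ms_bank_cpp")]]
List ms_bank_cpp(NumericVector tau_out, NumericVector tau_close,
                 double tau_in, double tau_open, double v_gate,
                 double v0, double h0,
                 double duration, double dt, bool with_sens) {
  const int n_steps = (int)std::ceil(duration / dt - 1e-9);
  const int n = n_steps + 1;
  const int u = tau_out.size();
  NumericMatrix V(n, u), H(n, u), DV(n, u);
  NumericMatrix SO(with_sens ? n : 1, with_sens ? u : 1);
  NumericMatrix SC(with_sens ? n : 1, with_sens ? u : 1);
  std::vector<double> so_buf(n), sc_buf(n);
  for (int c = 0; c < u; ++c) {
    MSDeriv f{tau_in, tau_out[c], tau_open, tau_close[c], v_gate, with_sens};
    f.init();
    rk4_path(f, v0, h0, dt, n_steps, with_sens,
             &V(0, c), &H(0, c), &DV(0, c),
             with_sens ? &SO(0, c) : so_buf.data(),
             with_sens ? &SC(0, c) : sc_buf.data());
  }
  return List::create(_["v"] = V, _["h"] = H, _["dv_dt"] = DV,
                      _["s_out"] = SO, _["s_close"] = SC,
                      _["n_samples"] = n);
}
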