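#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reduced-order network time stepper.
//
// The circuit is a single chain of edges (inertance + linear resistance +
// quadratic orifice loss) joining nodes at known elevations. Nodal mass
// balance (with prescribed swept-volume sources on the calf nodes) is
// solved implicitly for the piezometric head phi = p + rho g z each step;
// edge momentum is semi-implicit (friction and the linearized orifice loss
// taken at the new time level, coefficients frozen at the previous flow).
// All quantities are SI.

static inline double eff_area(double x, double travel, double a_leak,
                              double a_full) {
  double f = x / travel;
  if (f < 0) f = 0;
  if (f > 1) f = 1;
  double a = a_leak + (a_full - a_leak) * f;
  return a < a_full ? a : a_full;
}

// [[Rcpp::export]]
List vp_core_run(List disc, List forcing, List valves, List control) {
  NumericVector e_len = disc["edge_len"];     // m
  NumericVector e_area0 = disc["edge_area"];  // m^2 (resting)
  NumericVector e_R0 = disc["edge_R"];        // Pa.s/m^3 (resting linear)
  IntegerVector e_type = disc["edge_type"];   // 0 plain, 1 porous, 2 distal, 3 proximal
  IntegerVector e_calf = disc["edge_calf"];   // 0/1 deformable
  NumericVector e_smid = disc["edge_smid"];   // sin(psi) at edge midpoint
  NumericVector node_z = disc["node_z"];      // m
  NumericVector node_G = disc["node_G"];      // m^3, swept source coefficient

  int n_e = e_len.size();
  int n_n = node_z.size();
  if (n_n != n_e + 1) stop("node/edge count mismatch");

  double p_in_mean = forcing["p_in_mean"], p_in_amp = forcing["p_in_amp"];
  double T_in = forcing["T_in"], p_out = forcing["p_out"];
  int wm_on = forcing["wm_on"];
  double wm_a = forcing["wm_a"], wm_T0 = forcing["wm_T0"];
  double wm_rrest = forcing["wm_rrest"];

  IntegerVector v_edge = valves["edge"];      // length 0 or 2, 0-based
  NumericVector v_afull = valves["a_full"], v_aleak = valves["a_leak"];
  NumericVector v_travel = valves["travel"], v_kappa = valves["kappa"];
  NumericVector v_tau = valves["tau"], v_balld = valves["ball_d"];
  NumericVector v_ballrho = valves["ball_rho"];
  NumericVector v_x = clone(as<NumericVector>(valves["x0"]));
  int v_dyn = valves["dynamics"];             // 0 relaxation, 1 inertial
  int n_v = v_edge.size();

  double dt = control["dt"];
  int n_steps = control["n_steps"], sample_every = control["sample_every"];
  int scheme = control["scheme"];             // 0 semi-implicit, 1 explicit losses
  double t0 = control["t0"];
  NumericVector init_q = control["init_q"];   // length 1 (uniform) or n_e
  NumericVector init_p = control["init_p"];   // length 1 (uniform) or n_n, Pa
  double grav = control["gravity"], rho = control["rho"], eta = control["eta"];
  double compl_c = control["compliance"];     // m^3/Pa per node
  IntegerVector probe_nodes = control["probe_nodes"]; // 0-based
  IntegerVector probe_edges = control["probe_edges"]; // 0-based

  std::vector<double> Q(n_e), phi(n_n), a_e(n_e), b_e(n_e);
  std::vector<double> area(n_e), Rlin(n_e), Lin(n_e), Kq(n_e), S(n_n, 0.0);
  std::vector<double> v_vel(n_v, 0.0);
  for (int e = 0; e < n_e; ++e) Q[e] = init_q.size() == 1 ? init_q[0] : init_q[e];
  for (int i = 0; i < n_n; ++i) {
    double p_i = init_p.size() == 1 ? init_p[0] : init_p[i];
    phi[i] = p_i + rho * grav * node_z[i];
  }
  for (int e = 0; e < n_e; ++e) {
    area[e] = e_area0[e];
    Rlin[e] = e_R0[e];
    Lin[e] = e_len[e] > 0 ? rho * e_len[e] / area[e] : 0.0;
    Kq[e] = 0.0;
  }

  int n_samp = n_steps / sample_every + 1;
  NumericVector out_t(n_samp);
  NumericMatrix out_p(n_samp, probe_nodes.size());
  NumericMatrix out_q(n_samp, probe_edges.size());
  NumericMatrix out_x(n_samp, n_v), out_a(n_samp, n_v);
  NumericVector out_qin(n_samp), out_qout(n_samp), out_sw(n_samp);

  std::vector<double> low(n_n), dia(n_n), upp(n_n), rhs(n_n);

  double t = t0;
  double sw_rate = 0.0;
  int is = 0;
  auto record = [&](int k) {
    out_t[k] = t;
    for (int j = 0; j < probe_nodes.size(); ++j) {
      int i = probe_nodes[j];
      out_p(k, j) = phi[i] - rho * grav * node_z[i];
    }
    for (int j = 0; j < probe_edges.size(); ++j) out_q(k, j) = Q[probe_edges[j]];
    for (int v = 0; v < n_v; ++v) {
      out_x(k, v) = v_x[v];
      out_a(k, v) = eff_area(v_x[v], v_travel[v], v_aleak[v], v_afull[v]);
    }
    out_qin[k] = Q[0];
    out_qout[k] = Q[n_e - 1];
    out_sw[k] = sw_rate;
  };
  record(is++);

  for (int step = 1; step <= n_steps; ++step) {
    double tn = t0 + step * dt;

    // (1) calf wall kinematics at the new time level
    double vt = 0.0, ct = 1.0;
    if (wm_on) {
      double th = 2.0 * M_PI * tn / wm_T0;
      vt = std::sin(th) / wm_T0;
      ct = std::cos(th);
      for (int e = 0; e < n_e; ++e) {
        if (e_calf[e]) {
          double delta = 0.5 * wm_a * e_smid[e] * (1.0 - ct);
          double r = wm_rrest - delta;
          if (r <= 0) stop("calf lumen collapsed (non-positive radius)");
          double A = M_PI * r * r;
          area[e] = A;
          Rlin[e] = 8.0 * M_PI * eta * e_len[e] / (A * A);
          Lin[e] = rho * e_len[e] / A;
        }
      }
      for (int i = 0; i < n_n; ++i) S[i] = node_G[i] * vt;
      sw_rate = 0.0;
      for (int i = 0; i < n_n; ++i) sw_rate += S[i];
    }

    // (2) ball dynamics from the previous-step fields
    for (int v = 0; v < n_v; ++v) {
      int e = v_edge[v];
      double a_eff = eff_area(v_x[v], v_travel[v], v_aleak[v], v_afull[v]);
      double dphi = phi[e] - phi[e + 1]; // forward (heart-ward) difference
      double a_ball = M_PI * v_balld[v] * v_balld[v] / 4.0;
      double u_f = Q[e] / a_eff;
      double f = dphi * a_ball
        + 3.0 * M_PI * eta * v_balld[v] * (u_f - v_vel[v])
        - (v_ballrho[v] - rho) * (M_PI / 6.0) * std::pow(v_balld[v], 3) * grav;
      if (v_dyn == 0) {
        double x_inf = f > 0 ? v_travel[v] : (f < 0 ? 0.0 : v_x[v]);
        double x_new = x_inf + (v_x[v] - x_inf) * std::exp(-dt / v_tau[v]);
        v_vel[v] = (x_new - v_x[v]) / dt;
        v_x[v] = x_new;
      } else {
        double m = v_ballrho[v] * (M_PI / 6.0) * std::pow(v_balld[v], 3);
        v_vel[v] += f / m * dt;
        v_x[v] += v_vel[v] * dt;
      }
      if (v_x[v] < 0) { v_x[v] = 0; v_vel[v] = 0; }
      if (v_x[v] > v_travel[v]) { v_x[v] = v_travel[v]; v_vel[v] = 0; }
      a_eff = eff_area(v_x[v], v_travel[v], v_aleak[v], v_afull[v]);
      Rlin[e] = v_kappa[v] * (1.0 / a_eff - 1.0 / v_afull[v]);
      Kq[e] = 0.5 * rho / (a_eff * a_eff);
    }

    // (3) edge momentum coefficients: Q_new = a_e + b_e * (phi_i - phi_j)
    for (int e = 0; e < n_e; ++e) {
      double loss = Rlin[e] + Kq[e] * std::fabs(Q[e]);
      double denom, num;
      if (scheme == 0 || Lin[e] <= 0) {
        denom = Lin[e] / dt + loss;
        num = Lin[e] / dt * Q[e];
      } else {
        denom = Lin[e] / dt;
        num = Lin[e] / dt * Q[e] - loss * Q[e];
      }
      if (denom <= 0) stop("degenerate edge (zero inertance and resistance)");
      b_e[e] = 1.0 / denom;
      a_e[e] = num / denom;
    }

    // (4) boundary heads at the new time level
    double p_in = p_in_mean + p_in_amp * std::sin(2.0 * M_PI * tn / T_in);
    phi[0] = p_in + rho * grav * node_z[0];
    phi[n_n - 1] = p_out + rho * grav * node_z[n_n - 1];

    // (5) interior mass balance: tridiagonal solve for phi
    // b_i phi_{i-1} - (b_i + b_{i+1} + C/dt) phi_i + b_{i+1} phi_{i+1}
    //   = a_{i+1} - a_i - S_i - C/dt phi_i_old
    for (int i = 1; i < n_n - 1; ++i) {
      low[i] = b_e[i - 1];
      dia[i] = -(b_e[i - 1] + b_e[i] + compl_c / dt);
      upp[i] = b_e[i];
      rhs[i] = a_e[i] - a_e[i - 1] - S[i] - compl_c / dt * phi[i];
    }
    rhs[1] -= low[1] * phi[0];
    rhs[n_n - 2] -= upp[n_n - 2] * phi[n_n - 1];
    // Thomas elimination
    for (int i = 2; i < n_n - 1; ++i) {
      double w = low[i] / dia[i - 1];
      dia[i] -= w * upp[i - 1];
      rhs[i] -= w * rhs[i - 1];
    }
    if (n_n > 2) {
      phi[n_n - 2] = rhs[n_n - 2] / dia[n_n - 2];
      for (int i = n_n - 3; i >= 1; --i) {
        phi[i] = (rhs[i] - upp[i] * phi[i + 1]) / dia[i];
      }
    }

    // (6) new flows
    for (int e = 0; e < n_e; ++e) {
      Q[e] = a_e[e] + b_e[e] * (phi[e] - phi[e + 1]);
      if (!std::isfinite(Q[e])) {
        stop("numerical failure (non-finite flow) at t = %f s", t);
      }
    }
    t = tn;
    if (step % sample_every == 0) record(is++);
  }

  NumericVector fin_x(n_v), fin_v(n_v);
  for (int v = 0; v < n_v; ++v) { fin_x[v] = v_x[v]; fin_v[v] = v_vel[v]; }
  NumericVector fin_q(n_e), fin_p(n_n);
  for (int e = 0; e < n_e; ++e) fin_q[e] = Q[e];
  for (int i = 0; i < n_n; ++i) fin_p[i] = phi[i] - rho * grav * node_z[i];

  return List::create(_["time"] = out_t, _["p_probe"] = out_p,
                      _["q_probe"] = out_q, _["x_valve"] = out_x,
                      _["a_valve"] = out_a, _["q_inlet"] = out_qin,
                      _["q_outlet"] = out_qout, _["swept_rate"] = out_sw,
                      _["final_q"] = fin_q, _["final_p"] = fin_p,
                      _["final_x"] = fin_x, _["final_v"] = fin_v);
}
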