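#include <Rcpp.h>
using namespace Rcpp;

// Semi-implicit Euler integration of the two second-order wrist plants
// driven by per-hand PD feedback on cursor-target error, signal-dependent
// torque noise and (optionally) virtual-spring coupling. All angles are in
// radians here; the R wrapper converts to degrees for output.
//
// weighting: 0 = left, 1 = center, 2 = right
// mirror:    0 = none, 1 = left copies right's command, 2 = right copies left
// rigid:     kinematic constraint q_l == q_r with summed inertias
//
// Returns q_l, q_r (rad), w_l, w_r (rad/s) and the commanded net torques
// u_l, u_r (Nm, noise included) sampled after each step, plus an
// instability index (0 when stable).
// [[Rcpp::export(name = ".simulate_plant_cpp")]]
List simulate_plant_cpp(NumericVector q_target, NumericVector qd_target,
                        double dt, int weighting, bool rigid, double stiffness,
                        double coupling_damping,
                        double inertia_l, double inertia_r,
                        double viscosity_l, double viscosity_r,
                        double kp_l, double kd_l, double kp_r, double kd_r,
                        double share_l, double share_r, int mirror,
                        double noise_base,
                        double noise_mult_l, double noise_mult_r,
                        double cc_l, double cc_r,
                        NumericVector eps_l, NumericVector eps_r) {
  const int n = q_target.size();
  if (qd_target.size() != n || eps_l.size() != n || eps_r.size() != n)
    stop("target and noise series must have equal length");

  NumericVector ql(n), qr(n), wl_out(n), wr_out(n), ul_out(n), ur_out(n);
  double q_l = 0.0, q_r = 0.0, w_l = 0.0, w_r = 0.0;
  int unstable = 0;

  for (int i = 0; i < n; ++i) {
    double qc, qcd;
    if (weighting == 0)      { qc = q_l; qcd = w_l; }
    else if (weighting == 2) { qc = q_r; qcd = w_r; }
    else                     { qc = 0.5 * (q_l + q_r); qcd = 0.5 * (w_l + w_r); }

    const double err  = q_target[i] - qc;
    const double errd = qd_target[i] - qcd;

    double u_l = share_l * (kp_l * err + kd_l * errd);
    double u_r = share_r * (kp_r * err + kd_r * errd);
    if (mirror == 1)      u_l = u_r;
    else if (mirror == 2) u_r = u_l;

    // signal-dependent noise grows with total muscle activation, i.e. the
    // reciprocal command plus the tonic co-contraction of the pair
    u_l += (noise_base + noise_mult_l * (std::fabs(u_l) + cc_l)) * eps_l[i];
    u_r += (noise_base + noise_mult_r * (std::fabs(u_r) + cc_r)) * eps_r[i];

    if (rigid) {
      double w = w_l;  // w_l == w_r under the constraint
      w += dt * (u_l + u_r - (viscosity_l + viscosity_r) * w) /
           (inertia_l + inertia_r);
      double q = q_l + dt * w;
      q_l = q_r = q;
      w_l = w_r = w;
    } else {
      const double tc = stiffness * (q_r - q_l) + coupling_damping * (w_r - w_l);
      w_l += dt * (u_l + tc - viscosity_l * w_l) / inertia_l;
      w_r += dt * (u_r - tc - viscosity_r * w_r) / inertia_r;
      q_l += dt * w_l;
      q_r += dt * w_r;
    }

    ql[i] = q_l; qr[i] = q_r;
    wl_out[i] = w_l; wr_out[i] = w_r;
    ul_out[i] = u_l; ur_out[i] = u_r;

    if (std::fabs(q_l) > M_PI || std::fabs(q_r) > M_PI) {
      unstable = i + 1;
      break;
    }
  }

  return List::create(_["q_l"] = ql, _["q_r"] = qr,
                      _["w_l"] = wl_out, _["w_r"] = wr_out,
                      _["u_l"] = ul_out, _["u_r"] = ur_out,
                      _["unstable"] = unstable);
}
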