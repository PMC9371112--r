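// Lumped-parameter surrogate of a helmeted-head ground impact.
//
// Two rigid bodies (head, helmet shell) with 6 DOF each:
//  - ground contact on the helmet outer sphere: penalty normal force with
//    damping + regularized Coulomb friction (tanh slip law);
//  - liner coupling: n radial viscoelastic patch elements on the shell inner
//    sphere, active in compression only, each with a regularized Coulomb
//    friction element driven by the local sliding velocity;
//  - a weak centering spring/damper between body centers (implicit chin
//    strap, keeps the helmet captured).
// Gravity is excluded: the event lasts tens of milliseconds and contact
// forces dominate by orders of magnitude.
//
// Integrated with fixed-step explicit RK4; state output is decimated to the
// requested record rate with accelerations evaluated from the dynamics at
// the recorded states.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Body {
  double m;
  vec3 Idiag;     // principal inertia about CoG, body frame
  double r;       // contact-surface radius
};

struct Params {
  Body head, helmet;
  double r_in;                    // shell inner (liner) radius
  double k_lin, c_lin, mu_lin;    // per-patch liner element
  double h_lin;                   // dimensionless bottoming-out hardening
  double g0;                      // nominal liner gap r_in - r_head
  double k_gnd, c_gnd, mu_gnd;    // ground penalty contact
  double strap_k, strap_c;
  double v_eps;                   // friction regularization velocity
  mat patches;                    // 3 x n unit directions, helmet body frame
  vec3 n_gnd;                     // ground plane normal, world frame
  double d_gnd;                   // plane: dot(n, p) = d_gnd
  double pen_limit_lin, pen_limit_gnd;
};

// state layout (26): x_h v_h q_h w_h | x_m v_m q_m w_m
// quaternions (w,x,y,z), angular velocities in body frame.

inline mat33 quat_to_mat(const vec4& q) {
  double w = q(0), x = q(1), y = q(2), z = q(3);
  mat33 R;
  R(0,0) = 1 - 2*(y*y + z*z); R(0,1) = 2*(x*y - w*z);     R(0,2) = 2*(x*z + w*y);
  R(1,0) = 2*(x*y + w*z);     R(1,1) = 1 - 2*(x*x + z*z); R(1,2) = 2*(y*z - w*x);
  R(2,0) = 2*(x*z - w*y);     R(2,1) = 2*(y*z + w*x);     R(2,2) = 1 - 2*(x*x + y*y);
  return R;
}

inline vec4 quat_deriv(const vec4& q, const vec3& w_body) {
  // qdot = 0.5 * q (x) (0, w_body)
  double qw = q(0), qx = q(1), qy = q(2), qz = q(3);
  double wx = w_body(0), wy = w_body(1), wz = w_body(2);
  vec4 qd;
  qd(0) = 0.5 * (-qx*wx - qy*wy - qz*wz);
  qd(1) = 0.5 * ( qw*wx + qy*wz - qz*wy);
  qd(2) = 0.5 * ( qw*wy - qx*wz + qz*wx);
  qd(3) = 0.5 * ( qw*wz + qx*wy - qy*wx);
  return qd;
}

struct Dyn {
  vec3 a_h, a_m;            // CoG accelerations, world frame
  vec3 wd_h, wd_m;          // angular accelerations, body frames
  vec3 F_ext;               // total external (ground) force, world
  vec3 F_lin_head, F_lin_helmet;  // total liner force on each body
  double max_pen_lin, max_pen_gnd;
};

// Regularized Coulomb friction force given normal magnitude and slip velocity.
inline vec3 friction_force(double mu, double Fn, const vec3& vt, double v_eps) {
  double s = norm(vt);
  if (s < 1e-14 || mu <= 0.0 || Fn <= 0.0) return vec3(fill::zeros);
  vec3 out = vt;
  out *= -mu * Fn * std::tanh(s / v_eps) / s;
  return out;
}

Dyn dynamics(const vec& y, const Params& P) {
  vec3 x_h = y.subvec(0, 2),  v_h = y.subvec(3, 5);
  vec4 q_h = y.subvec(6, 9);
  vec3 w_h = y.subvec(10, 12);
  vec3 x_m = y.subvec(13, 15), v_m = y.subvec(16, 18);
  vec4 q_m = y.subvec(19, 22);
  vec3 w_m = y.subvec(23, 25);

  mat33 R_h = quat_to_mat(normalise(q_h));
  mat33 R_m = quat_to_mat(normalise(q_m));
  vec3 wh_w = R_h * w_h;          // world-frame angular velocities
  vec3 wm_w = R_m * w_m;

  vec3 F_h(fill::zeros), F_m(fill::zeros);
  vec3 T_h(fill::zeros), T_m(fill::zeros);   // world torques about CoG

  Dyn out;
  out.F_ext.zeros();
  out.F_lin_head.zeros();
  out.F_lin_helmet.zeros();
  out.max_pen_lin = 0.0;
  out.max_pen_gnd = 0.0;

  // ---- ground contact on helmet outer sphere ----
  double s = dot(P.n_gnd, x_m) - P.d_gnd;      // center-to-plane distance
  double pen = P.helmet.r - s;
  if (pen > 0.0) {
    out.max_pen_gnd = pen;
    vec3 p_c = x_m - P.helmet.r * P.n_gnd;
    vec3 v_pc = v_m + cross(wm_w, p_c - x_m);
    double vn = dot(P.n_gnd, v_pc);            // >0 means separating
    double Fn = P.k_gnd * pen - P.c_gnd * vn;
    if (Fn < 0.0) Fn = 0.0;
    vec3 vt = v_pc - vn * P.n_gnd;
    vec3 F = Fn * P.n_gnd + friction_force(P.mu_gnd, Fn, vt, P.v_eps);
    F_m += F;
    T_m += cross(p_c - x_m, F);
    out.F_ext += F;
  }

  // ---- liner patches between head sphere and shell inner sphere ----
  const uword n_patch = P.patches.n_cols;
  for (uword i = 0; i < n_patch; ++i) {
    vec3 d_b = P.patches.col(i);
    vec3 r_m = R_m * (P.r_in * d_b);           // patch offset, world
    vec3 q_i = x_m + r_m;                      // shell inner-surface point
    vec3 e = q_i - x_h;
    double L = norm(e);
    double pen_i = P.r_in - L;
    if (pen_i <= 0.0) continue;
    if (pen_i > out.max_pen_lin) out.max_pen_lin = pen_i;
    vec3 eh = e / L;
    vec3 v_qi = v_m + cross(wm_w, r_m);
    double Ldot = dot(eh, v_qi - v_h);
    double frac = pen_i / P.g0;
    double Fn = P.k_lin * pen_i * (1.0 + P.h_lin * frac * frac) +
                P.c_lin * (-Ldot);
    if (Fn < 0.0) Fn = 0.0;
    // normal: pushes head away from the patch, shell outward
    vec3 Fn_head = -Fn * eh;
    // friction from head-surface slip relative to the shell point
    vec3 p_h = x_h + P.head.r * eh;
    vec3 v_ph = v_h + cross(wh_w, p_h - x_h);
    vec3 vrel = v_ph - v_qi;
    vec3 vt = vrel - dot(eh, vrel) * eh;
    vec3 Ff_head = friction_force(P.mu_lin, Fn, vt, P.v_eps);
    vec3 F_head = Fn_head + Ff_head;
    F_h += F_head;
    T_h += cross(p_h - x_h, F_head);
    F_m -= F_head;
    T_m += cross(q_i - x_m, -F_head);
    out.F_lin_head += F_head;
    out.F_lin_helmet += -F_head;
  }

  // ---- implicit chin strap: weak centering spring between centers ----
  vec3 F_s = -P.strap_k * (x_m - x_h) - P.strap_c * (v_m - v_h);
  F_m += F_s;
  F_h -= F_s;

  out.a_h = F_h / P.head.m;
  out.a_m = F_m / P.helmet.m;
  vec3 Iw_h = P.head.Idiag % w_h;
  vec3 Iw_m = P.helmet.Idiag % w_m;
  out.wd_h = (R_h.t() * T_h - cross(w_h, Iw_h)) / P.head.Idiag;
  out.wd_m = (R_m.t() * T_m - cross(w_m, Iw_m)) / P.helmet.Idiag;
  return out;
}

typedef vec::fixed<26> state26;

state26 deriv_from_dyn(const vec& y, const Dyn& d) {
  state26 dy;
  dy.subvec(0, 2) = y.subvec(3, 5);
  dy.subvec(3, 5) = d.a_h;
  dy.subvec(6, 9) = quat_deriv(y.subvec(6, 9), y.subvec(10, 12));
  dy.subvec(10, 12) = d.wd_h;
  dy.subvec(13, 15) = y.subvec(16, 18);
  dy.subvec(16, 18) = d.a_m;
  dy.subvec(19, 22) = quat_deriv(y.subvec(19, 22), y.subvec(23, 25));
  dy.subvec(23, 25) = d.wd_m;
  return dy;
}

state26 rhs(const vec& y, const Params& P) {
  return deriv_from_dyn(y, dynamics(y, P));
}

Body body_from_list(const Rcpp::List& b) {
  Body out;
  out.m = Rcpp::as<double>(b["mass"]);
  out.Idiag = Rcpp::as<vec>(b["inertia_diag"]);
  out.r = Rcpp::as<double>(b["radius"]);
  return out;
}

double kinetic_energy(const vec& y, const Params& P) {
  vec3 v_h = y.subvec(3, 5), w_h = y.subvec(10, 12);
  vec3 v_m = y.subvec(16, 18), w_m = y.subvec(23, 25);
  return 0.5 * P.head.m * dot(v_h, v_h) +
         0.5 * dot(w_h, P.head.Idiag % w_h) +
         0.5 * P.helmet.m * dot(v_m, v_m) +
         0.5 * dot(w_m, P.helmet.Idiag % w_m);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_simulate(Rcpp::List head, Rcpp::List helmet, Rcpp::List contact,
                        arma::mat patches, arma::vec n_gnd, double initial_gap,
                        arma::vec v0, double duration, double dt, double dt_out) {
  Params P;
  P.head = body_from_list(head);
  P.helmet = body_from_list(helmet);
  P.r_in = Rcpp::as<double>(helmet["inner_radius"]);
  P.k_lin = Rcpp::as<double>(contact["liner_stiffness"]);
  P.c_lin = Rcpp::as<double>(contact["liner_damping"]);
  P.mu_lin = Rcpp::as<double>(contact["liner_friction_mu"]);
  P.h_lin = Rcpp::as<double>(contact["liner_hardening"]);
  P.k_gnd = Rcpp::as<double>(contact["ground_stiffness"]);
  P.c_gnd = Rcpp::as<double>(contact["ground_damping"]);
  P.mu_gnd = Rcpp::as<double>(contact["ground_friction_mu"]);
  P.strap_k = Rcpp::as<double>(contact["strap_stiffness"]);
  P.strap_c = Rcpp::as<double>(contact["strap_damping"]);
  P.v_eps = Rcpp::as<double>(contact["v_eps"]);
  P.patches = patches;
  P.n_gnd = normalise(n_gnd);
  // bodies start concentric at the origin; plane tangent to the outer
  // sphere minus any initial gap
  P.d_gnd = -(P.helmet.r + initial_gap);
  P.g0 = P.r_in - P.head.r;
  P.pen_limit_lin = 0.95 * P.g0;
  P.pen_limit_gnd = 0.05;

  const int n_steps = (int) std::round(duration / dt);
  const int decim = std::max(1, (int) std::round(dt_out / dt));
  const int n_out = n_steps / decim + 1;

  state26 y;
  y.zeros();
  y.subvec(3, 5) = v0;
  y(6) = 1.0;  y(19) = 1.0;          // identity quaternions
  y.subvec(16, 18) = v0;

  // output buffers: per body, pose + kinematics history
  mat t_out(1, n_out);
  mat xh(3, n_out), vh(3, n_out), qh(4, n_out), wh(3, n_out), ah(3, n_out), wdh(3, n_out);
  mat xm(3, n_out), vm(3, n_out), qm(4, n_out), wm(3, n_out), am(3, n_out), wdm(3, n_out);

  double ke0 = kinetic_energy(y, P);
  vec3 mom0 = P.head.m * vec3(y.subvec(3, 5)) + P.helmet.m * vec3(y.subvec(16, 18));
  vec3 impulse(fill::zeros);
  vec3 F_prev(fill::zeros);
  double newton_resid = 0.0, max_pen_lin = 0.0, max_pen_gnd = 0.0;

  int i_out = 0;
  for (int step = 0; step <= n_steps; ++step) {
    Dyn d = dynamics(y, P);
    if (!y.is_finite()) {
      Rcpp::stop("solver diverged (non-finite state) at step %d (t = %.6f s)",
                 step, step * dt);
    }
    if (d.max_pen_lin > P.pen_limit_lin) {
      Rcpp::stop("liner interpenetration %.4f m beyond limit at t = %.6f s",
                 d.max_pen_lin, step * dt);
    }
    if (d.max_pen_gnd > P.pen_limit_gnd) {
      Rcpp::stop("ground interpenetration %.4f m beyond limit at t = %.6f s",
                 d.max_pen_gnd, step * dt);
    }
    double resid = norm(d.F_lin_head + d.F_lin_helmet);
    if (resid > newton_resid) newton_resid = resid;
    if (d.max_pen_lin > max_pen_lin) max_pen_lin = d.max_pen_lin;
    if (d.max_pen_gnd > max_pen_gnd) max_pen_gnd = d.max_pen_gnd;

    if (step % decim == 0 && i_out < n_out) {
      t_out(0, i_out) = step * dt;
      xh.col(i_out) = y.subvec(0, 2);   vh.col(i_out) = y.subvec(3, 5);
      qh.col(i_out) = y.subvec(6, 9);   wh.col(i_out) = y.subvec(10, 12);
      ah.col(i_out) = d.a_h;            wdh.col(i_out) = d.wd_h;
      xm.col(i_out) = y.subvec(13, 15); vm.col(i_out) = y.subvec(16, 18);
      qm.col(i_out) = y.subvec(19, 22); wm.col(i_out) = y.subvec(23, 25);
      am.col(i_out) = d.a_m;            wdm.col(i_out) = d.wd_m;
      ++i_out;
    }
    if (step == n_steps) break;

    // trapezoidal impulse of the external (ground) force
    impulse += 0.5 * (F_prev + d.F_ext) * dt;
    F_prev = d.F_ext;

    // RK4 step; k1 reuses the dynamics evaluation above
    state26 k1 = deriv_from_dyn(y, d);
    state26 k2 = rhs(y + (0.5 * dt) * k1, P);
    state26 k3 = rhs(y + (0.5 * dt) * k2, P);
    state26 k4 = rhs(y + dt * k3, P);
    y += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    y.subvec(6, 9) = normalise(vec4(y.subvec(6, 9)));
    y.subvec(19, 22) = normalise(vec4(y.subvec(19, 22)));
  }

  double ke1 = kinetic_energy(y, P);
  vec3 mom1 = P.head.m * vec3(y.subvec(3, 5)) + P.helmet.m * vec3(y.subvec(16, 18));

  auto body_hist = [](const mat& x, const mat& v, const mat& q, const mat& w,
                      const mat& a, const mat& wd) {
    return Rcpp::List::create(
      Rcpp::Named("x") = x, Rcpp::Named("v") = v, Rcpp::Named("quat") = q,
      Rcpp::Named("omega_body") = w, Rcpp::Named("a_world") = a,
      Rcpp::Named("alpha_body") = wd);
  };

  return Rcpp::List::create(
    Rcpp::Named("time") = vec(t_out.row(0).t()),
    Rcpp::Named("head") = body_hist(xh, vh, qh, wh, ah, wdh),
    Rcpp::Named("helmet") = body_hist(xm, vm, qm, wm, am, wdm),
    Rcpp::Named("diagnostics") = Rcpp::List::create(
      Rcpp::Named("ke_start") = ke0,
      Rcpp::Named("ke_end") = ke1,
      Rcpp::Named("impulse") = vec(impulse),
      Rcpp::Named("momentum_change") = vec(mom1 - mom0),
      Rcpp::Named("newton_residual") = newton_resid,
      Rcpp::Named("max_pen_liner") = max_pen_lin,
      Rcpp::Named("max_pen_ground") = max_pen_gnd));
}

// Body-frame coordinate acceleration of a body-fixed point:
// a_p = R^T a_cg + alpha x r + w x (w x r), everything in the body frame.
// [[Rcpp::export]]
arma::mat cpp_point_acceleration(const arma::mat& quat, const arma::mat& a_world,
                                 const arma::mat& alpha_body,
                                 const arma::mat& omega_body,
                                 const arma::vec& point) {
  const uword T = quat.n_cols;
  mat out(3, T);
  vec3 r = point;
  for (uword t = 0; t < T; ++t) {
    mat33 R = quat_to_mat(normalise(vec4(quat.col(t))));
    vec3 a_b = R.t() * vec3(a_world.col(t));
    vec3 al = alpha_body.col(t);
    vec3 w = omega_body.col(t);
    out.col(t) = a_b + cross(al, r) + cross(w, cross(w, r));
  }
  return out;
}
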