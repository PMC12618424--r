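// Compiled core of the coupled 0D solver: residual/Jacobian assembly,
// damped Newton time stepping with step-halving fallback, full-cycle
// forward marches, and the backward (adjoint) sweep. Mirrors the R
// reference assembly in R/solver.R; a consistency test ties the two.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NS = 28;
static const double A_FLOOR = 1e-4;

// valve wiring (0-based): q, z, up, dn  (mit, aor, tri, pul)
static const int VW[4][4] = {{1, 2, 0, 5}, {3, 4, 5, 6},
                             {11, 12, 10, 15}, {13, 14, 15, 16}};
// chamber wiring: V, tau, p, q_in, q_out  (la, lv, ra, rv)
static const int CW[4][5] = {{20, 24, 0, 19, 1}, {21, 25, 5, 1, 3},
                             {22, 26, 10, 9, 11}, {23, 27, 15, 11, 13}};
// windkessel wiring: p_ar, q_valve, q_ar, p_ven, q_ven, p_at_down
static const int WK[2][6] = {{6, 3, 7, 8, 9, 10}, {16, 13, 17, 18, 19, 0}};

struct Params {
  double wk[2][5];   // C_ar, R_ar, Z_ar, C_ven, R_ven (sys, pul)
  double pv[4][6];   // A_min, A_max, K_vo, K_vc, l_eff, rho
  double ch[4][4];   // V_ref, E_pass_a, E_pass_b, wall_factor
  double theta;
};

static Params unpack(const Rcpp::NumericVector& flat) {
  Params p;
  int k = 0;
  for (int s = 0; s < 2; ++s) for (int j = 0; j < 5; ++j) p.wk[s][j] = flat[k++];
  for (int v = 0; v < 4; ++v) for (int j = 0; j < 6; ++j) p.pv[v][j] = flat[k++];
  for (int c = 0; c < 4; ++c) for (int j = 0; j < 4; ++j) p.ch[c][j] = flat[k++];
  p.theta = flat[k++];
  return p;
}

// residual and (optionally) Jacobians of one One-Step-theta step.
// branch: nullptr derives the valve branch from xn, else 0/1 per valve.
static void assemble(const vec& xn, const vec& xp, const Params& P,
                     double dt, const vec& au_n, const vec& su_n,
                     const vec& au_p, const vec& su_p,
                     vec& r, mat* A, mat* B, const int* branch) {
  const double th = P.theta, th1 = 1.0 - th;
  r.zeros(NS);
  if (A) A->zeros(NS, NS);
  if (B) B->zeros(NS, NS);

  for (int v = 0; v < 4; ++v) {
    const int qi = VW[v][0], zi = VW[v][1], ui = VW[v][2], di = VW[v][3];
    const double Amin = P.pv[v][0], Amax = P.pv[v][1];
    const double Kvo = P.pv[v][2], Kvc = P.pv[v][3];
    const double l = P.pv[v][4], rho = P.pv[v][5];
    const double dA = Amax - Amin;
    const double dpn = xn(ui) - xn(di), dpp = xp(ui) - xp(di);
    const double An_raw = dA * xn(zi) + Amin, Ap_raw = dA * xp(zi) + Amin;
    const double An = std::max(An_raw, A_FLOOR), Ap = std::max(Ap_raw, A_FLOOR);
    const double dAdz_n = (An_raw > A_FLOOR) ? dA : 0.0;
    const double dAdz_p = (Ap_raw > A_FLOOR) ? dA : 0.0;
    const int rm = 2 * v, rz = 2 * v + 1;
    r(rm) = rho * l / An * (xn(qi) - xp(qi)) / dt
      - th * (dpn - rho / (2 * An * An) * xn(qi) * std::abs(xn(qi)))
      - th1 * (dpp - rho / (2 * Ap * Ap) * xp(qi) * std::abs(xp(qi)));
    const bool open_n = branch ? (branch[v] != 0) : (dpn > 0);
    const bool open_p = dpp > 0;
    const double rate_n = open_n ? (1 - xn(zi)) * Kvo * dpn : xn(zi) * Kvc * dpn;
    const double rate_p = open_p ? (1 - xp(zi)) * Kvo * dpp : xp(zi) * Kvc * dpp;
    r(rz) = (xn(zi) - xp(zi)) / dt - th * rate_n - th1 * rate_p;
    if (A) {
      (*A)(rm, qi) = rho * l / (An * dt) + th * rho * std::abs(xn(qi)) / (An * An);
      (*A)(rm, ui) = -th; (*A)(rm, di) = th;
      (*A)(rm, zi) = (-rho * l * (xn(qi) - xp(qi)) / (An * An * dt)
                      - th * rho * xn(qi) * std::abs(xn(qi)) / (An * An * An)) * dAdz_n;
      (*B)(rm, qi) = -rho * l / (An * dt) + th1 * rho * std::abs(xp(qi)) / (Ap * Ap);
      (*B)(rm, ui) = -th1; (*B)(rm, di) = th1;
      (*B)(rm, zi) = -th1 * rho * xp(qi) * std::abs(xp(qi)) / (Ap * Ap * Ap) * dAdz_p;
      const double drdz_n = open_n ? -Kvo * dpn : Kvc * dpn;
      const double drddp_n = open_n ? (1 - xn(zi)) * Kvo : xn(zi) * Kvc;
      const double drdz_p = open_p ? -Kvo * dpp : Kvc * dpp;
      const double drddp_p = open_p ? (1 - xp(zi)) * Kvo : xp(zi) * Kvc;
      (*A)(rz, zi) = 1.0 / dt - th * drdz_n;
      (*A)(rz, ui) = -th * drddp_n; (*A)(rz, di) = th * drddp_n;
      (*B)(rz, zi) = -1.0 / dt - th1 * drdz_p;
      (*B)(rz, ui) = -th1 * drddp_p; (*B)(rz, di) = th1 * drddp_p;
    }
  }

  for (int s = 0; s < 2; ++s) {
    const double C_ar = P.wk[s][0], R_ar = P.wk[s][1], Z_ar = P.wk[s][2];
    const double C_ven = P.wk[s][3], R_ven = P.wk[s][4];
    const int p_ar = WK[s][0], q_v = WK[s][1], q_ar = WK[s][2];
    const int p_ven = WK[s][3], q_ven = WK[s][4], p_at = WK[s][5];
    const int b0 = 8 + 4 * s;
    r(b0) = C_ar * ((xn(p_ar) - xp(p_ar)) / dt - Z_ar * (xn(q_v) - xp(q_v)) / dt)
      + th * (-xn(q_v) + xn(q_ar)) + th1 * (-xp(q_v) + xp(q_ar));
    r(b0 + 1) = (xn(p_ven) - xn(p_ar) + Z_ar * xn(q_v)) / R_ar + xn(q_ar);
    r(b0 + 2) = C_ven * (xn(p_ven) - xp(p_ven)) / dt
      + th * (-xn(q_ar) + xn(q_ven)) + th1 * (-xp(q_ar) + xp(q_ven));
    r(b0 + 3) = (xn(p_at) - xn(p_ven)) / R_ven + xn(q_ven);
    if (A) {
      (*A)(b0, p_ar) = C_ar / dt;
      (*A)(b0, q_v) = -C_ar * Z_ar / dt - th;
      (*A)(b0, q_ar) = th;
      (*B)(b0, p_ar) = -C_ar / dt;
      (*B)(b0, q_v) = C_ar * Z_ar / dt - th1;
      (*B)(b0, q_ar) = th1;
      (*A)(b0 + 1, p_ven) = 1.0 / R_ar;
      (*A)(b0 + 1, p_ar) = -1.0 / R_ar;
      (*A)(b0 + 1, q_v) = Z_ar / R_ar;
      (*A)(b0 + 1, q_ar) = 1.0;
      (*A)(b0 + 2, p_ven) = C_ven / dt;
      (*A)(b0 + 2, q_ar) = -th; (*A)(b0 + 2, q_ven) = th;
      (*B)(b0 + 2, p_ven) = -C_ven / dt;
      (*B)(b0 + 2, q_ar) = -th1; (*B)(b0 + 2, q_ven) = th1;
      (*A)(b0 + 3, p_at) = 1.0 / R_ven;
      (*A)(b0 + 3, p_ven) = -1.0 / R_ven;
      (*A)(b0 + 3, q_ven) = 1.0;
    }
  }

  for (int c = 0; c < 4; ++c) {
    const int Vi = CW[c][0], ti = CW[c][1], pi = CW[c][2];
    const int qin = CW[c][3], qout = CW[c][4];
    const double Vref = P.ch[c][0], a = P.ch[c][1], b = P.ch[c][2],
                 wf = P.ch[c][3];
    const int rmass = 16 + c, rclos = 20 + c, rtau = 24 + c;
    r(rmass) = (xn(Vi) - xp(Vi)) / dt
      + th * (-xn(qin) + xn(qout)) + th1 * (-xp(qin) + xp(qout));
    const double e = std::exp(b * (xn(Vi) - Vref));
    const double ratio = std::cbrt(xn(Vi) / Vref);
    const double pc = a * (e - 1.0) + wf * xn(ti) * ratio;
    r(rclos) = xn(pi) - pc;
    r(rtau) = (xn(ti) - xp(ti)) / dt
      - th * (-au_n(c) * xn(ti) + su_n(c))
      - th1 * (-au_p(c) * xp(ti) + su_p(c));
    if (A) {
      (*A)(rmass, Vi) = 1.0 / dt;
      (*A)(rmass, qin) = -th; (*A)(rmass, qout) = th;
      (*B)(rmass, Vi) = -1.0 / dt;
      (*B)(rmass, qin) = -th1; (*B)(rmass, qout) = th1;
      (*A)(rclos, pi) = 1.0;
      (*A)(rclos, Vi) = -(a * b * e + wf * xn(ti) * ratio / (3.0 * xn(Vi)));
      (*A)(rclos, ti) = -wf * ratio;
      (*A)(rtau, ti) = 1.0 / dt + th * au_n(c);
      (*B)(rtau, ti) = -1.0 / dt + th1 * au_p(c);
    }
  }
}

static const double XS[NS] = {1, 1e4, 1, 1e4, 1, 1, 1, 1e4, 1, 1e4,
                              1, 1e4, 1, 1e4, 1, 1, 1, 1e4, 1, 1e4,
                              1e4, 1e4, 1e4, 1e4, 1, 1, 1, 1};

static double scaled_norm(const vec& r, const vec& rs) {
  return max(abs(r) / rs);
}

// one implicit step; on nonconvergence recurse with halved dt using
// linearly interpolated activation tables. Throws on final failure.
static vec newton_step_core(const vec& xp, const Params& P, double dt,
                            const vec& au_n, const vec& su_n,
                            const vec& au_p, const vec& su_p,
                            double tol, int max_iter, int depth) {
  vec xn = xp, r(NS);
  mat A(NS, NS), B(NS, NS);
  vec xsv(NS);
  for (int i = 0; i < NS; ++i) xsv(i) = XS[i];
  assemble(xn, xp, P, dt, au_n, su_n, au_p, su_p, r, &A, &B, nullptr);
  vec rs = clamp(abs(A) * xsv, 1e-8, datum::inf);
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    if (scaled_norm(r, rs) < tol) { converged = true; break; }
    int branch[4];
    for (int v = 0; v < 4; ++v)
      branch[v] = (xn(VW[v][2]) - xn(VW[v][3]) > 0) ? 1 : 0;
    assemble(xn, xp, P, dt, au_n, su_n, au_p, su_p, r, &A, &B, branch);
    if (scaled_norm(r, rs) < tol) { converged = true; break; }
    vec dx;
    bool ok = solve(dx, A, -r);
    if (!ok || !dx.is_finite()) break;
    double lam = 1.0;
    const double n0 = scaled_norm(r, rs);
    for (int h = 0; h <= 4; ++h) {
      vec xtry = xn + lam * dx;
      for (int v = 0; v < 4; ++v) {
        int zi = VW[v][1];
        xtry(zi) = std::min(1.0, std::max(0.0, xtry(zi)));
      }
      bool vol_ok = true;
      for (int c = 0; c < 4; ++c) if (xtry(CW[c][0]) <= 0) vol_ok = false;
      if (vol_ok) {
        vec rtry(NS);
        assemble(xtry, xp, P, dt, au_n, su_n, au_p, su_p, rtry,
                 nullptr, nullptr, branch);
        if (rtry.is_finite() && (scaled_norm(rtry, rs) < n0 || h == 4)) {
          xn = xtry; r = rtry;
          break;
        }
      }
      lam *= 0.5;
    }
  }
  if (!converged && scaled_norm(r, rs) >= tol) {
    if (depth >= 4)
      Rcpp::stop("Newton failed to converge (scaled residual %g)",
                 scaled_norm(r, rs));
    const vec au_m = 0.5 * (au_n + au_p), su_m = 0.5 * (su_n + su_p);
    vec xh = newton_step_core(xp, P, dt / 2, au_m, su_m, au_p, su_p,
                              tol, max_iter, depth + 1);
    return newton_step_core(xh, P, dt / 2, au_n, su_n, au_m, su_m,
                            tol, max_iter, depth + 1);
  }
  return xn;
}

// [[Rcpp::export(name = ".cpp_assemble")]]
Rcpp::List cpp_assemble(Rcpp::NumericVector xn_, Rcpp::NumericVector xp_,
                        Rcpp::NumericVector flat, double dt,
                        Rcpp::NumericVector au_n, Rcpp::NumericVector su_n,
                        Rcpp::NumericVector au_p, Rcpp::NumericVector su_p,
                        bool jacobian) {
  Params P = unpack(flat);
  vec xn(xn_.begin(), NS), xp(xp_.begin(), NS);
  vec aun(au_n.begin(), 4), sun(su_n.begin(), 4);
  vec aup(au_p.begin(), 4), sup(su_p.begin(), 4);
  vec r(NS);
  if (!jacobian) {
    assemble(xn, xp, P, dt, aun, sun, aup, sup, r, nullptr, nullptr, nullptr);
    return Rcpp::List::create(Rcpp::Named("r") = r);
  }
  mat A(NS, NS), B(NS, NS);
  assemble(xn, xp, P, dt, aun, sun, aup, sup, r, &A, &B, nullptr);
  return Rcpp::List::create(Rcpp::Named("r") = r, Rcpp::Named("A") = A,
                            Rcpp::Named("B") = B);
}

// [[Rcpp::export(name = ".cpp_newton_step")]]
Rcpp::NumericVector cpp_newton_step(Rcpp::NumericVector xp_,
                                    Rcpp::NumericVector flat, double dt,
                                    Rcpp::NumericVector au_n,
                                    Rcpp::NumericVector su_n,
                                    Rcpp::NumericVector au_p,
                                    Rcpp::NumericVector su_p,
                                    double tol, int max_iter) {
  Params P = unpack(flat);
  vec xp(xp_.begin(), NS);
  vec aun(au_n.begin(), 4), sun(su_n.begin(), 4);
  vec aup(au_p.begin(), 4), sup(su_p.begin(), 4);
  vec x = newton_step_core(xp, P, dt, aun, sun, aup, sup, tol, max_iter, 0);
  return Rcpp::NumericVector(x.begin(), x.end());
}

// full-cycle forward march; au/su are 4 x (n+1) matrices on the grid
// [[Rcpp::export(name = ".cpp_forward_cycle")]]
Rcpp::NumericMatrix cpp_forward_cycle(Rcpp::NumericVector x0_,
                                      Rcpp::NumericVector flat, double dt,
                                      Rcpp::NumericMatrix au,
                                      Rcpp::NumericMatrix su,
                                      double tol, int max_iter) {
  Params P = unpack(flat);
  const int n = au.ncol() - 1;
  mat AU(au.begin(), 4, n + 1, false), SU(su.begin(), 4, n + 1, false);
  Rcpp::NumericMatrix out(n + 1, NS);
  vec x(x0_.begin(), NS);
  for (int i = 0; i < NS; ++i) out(0, i) = x(i);
  for (int k = 0; k < n; ++k) {
    x = newton_step_core(x, P, dt, AU.col(k + 1), SU.col(k + 1),
                         AU.col(k), SU.col(k), tol, max_iter, 0);
    for (int i = 0; i < NS; ++i) out(k + 1, i) = x(i);
  }
  return out;
}

// discrete adjoint backward sweep; returns the 12-gradient
// (parameter blocks ordered rv, lv, ra, la as in the fit vector).
// tabs arrays are 4 x (n+1): au, su, sgn, H, aup, dmax, dmin.
// gmat is (n+1) x 28 holding df/dx at each step.
// [[Rcpp::export(name = ".cpp_adjoint_sweep")]]
Rcpp::NumericVector cpp_adjoint_sweep(Rcpp::NumericMatrix states_,
                                      Rcpp::NumericVector flat, double dt,
                                      Rcpp::NumericMatrix au_,
                                      Rcpp::NumericMatrix su_,
                                      Rcpp::NumericMatrix sgn_,
                                      Rcpp::NumericMatrix H_,
                                      Rcpp::NumericMatrix aup_,
                                      Rcpp::NumericMatrix dmax_,
                                      Rcpp::NumericMatrix dmin_,
                                      Rcpp::NumericVector sigma0_,
                                      Rcpp::NumericMatrix gmat_,
                                      Rcpp::IntegerVector phi_block_) {
  Params P = unpack(flat);
  const int n = states_.nrow() - 1;
  mat states(states_.begin(), n + 1, NS, false);
  mat AU(au_.begin(), 4, n + 1, false), SU(su_.begin(), 4, n + 1, false);
  mat SG(sgn_.begin(), 4, n + 1, false), HH(H_.begin(), 4, n + 1, false);
  mat AUP(aup_.begin(), 4, n + 1, false);
  mat DMX(dmax_.begin(), 4, n + 1, false), DMN(dmin_.begin(), 4, n + 1, false);
  mat gmat(gmat_.begin(), n + 1, NS, false);
  const double th = P.theta, th1 = 1.0 - th;
  vec grad(12, fill::zeros);
  vec lam_next; mat B_next;
  mat A(NS, NS), B(NS, NS);
  vec r(NS);
  for (int k = n; k >= 1; --k) {
    vec xn = states.row(k).t(), xp = states.row(k - 1).t();
    assemble(xn, xp, P, dt, AU.col(k), SU.col(k), AU.col(k - 1),
             SU.col(k - 1), r, &A, &B, nullptr);
    vec rhs = -gmat.row(k).t();
    if (lam_next.n_elem) rhs -= B_next.t() * lam_next;
    vec lam = solve(A.t(), rhs);
    for (int c = 0; c < 4; ++c) {
      const double tau_n = xn(CW[c][1]), tau_p = xp(CW[c][1]);
      const double l_tau = lam(24 + c);
      const double s0 = sigma0_[c];
      const double dr_dsig = -th * AUP(c, k) - th1 * AUP(c, k - 1);
      const double dr_dun = th * (SG(c, k) * tau_n - s0 * HH(c, k));
      const double dr_dup = th1 * (SG(c, k - 1) * tau_p - s0 * HH(c, k - 1));
      const double dr_damax = dr_dun * DMX(c, k) + dr_dup * DMX(c, k - 1);
      const double dr_damin = dr_dun * DMN(c, k) + dr_dup * DMN(c, k - 1);
      const int j = 3 * (phi_block_[c] - 1);
      grad(j) += l_tau * dr_dsig;
      grad(j + 1) += l_tau * dr_damax;
      grad(j + 2) += l_tau * dr_damin;
    }
    lam_next = lam; B_next = B;
  }
  return Rcpp::NumericVector(grad.begin(), grad.end());
}
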