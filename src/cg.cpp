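// Coarse-grained force-field evaluation and the two dynamics engines
// (biased overdamped Langevin "ratchet-and-pawl" integrator and the
// Metropolis Monte Carlo engine with crankshaft/Cartesian/pivot moves),
// plus the Onsager-Machlup path log-weight.  Energies are in units of kT
// at the reference temperature, lengths in Angstrom.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct FF {
  int n;
  std::vector<int> b_i, b_j;               std::vector<double> b0;
  std::vector<int> a_i, a_j, a_k;          std::vector<double> th0;
  std::vector<int> d_i, d_j, d_k, d_l;     std::vector<double> ph0;
  double kb, ka, kd1, kd3;
  std::vector<int> n_i, n_j;               std::vector<double> n_sig, n_eps;
  std::vector<int> p_i, p_j;               std::vector<double> p_eqc, p_qq;
  std::vector<char> p_ev;
  double lB, lambdaD, r_qc, w_qc, sig_ev, eps_ev;
  std::vector<std::vector<int>> nat_adj, pair_adj, bond_adj, ang_adj, dih_adj;
};

static std::vector<int> ivec(SEXP s) {
  IntegerVector v(s);
  return std::vector<int>(v.begin(), v.end());
}
static std::vector<double> dvec(SEXP s) {
  NumericVector v(s);
  return std::vector<double>(v.begin(), v.end());
}

static FF make_ff(List spec) {
  FF ff;
  ff.n = as<int>(spec["n"]);
  ff.b_i = ivec(spec["b_i"]); ff.b_j = ivec(spec["b_j"]); ff.b0 = dvec(spec["b0"]);
  ff.a_i = ivec(spec["a_i"]); ff.a_j = ivec(spec["a_j"]); ff.a_k = ivec(spec["a_k"]);
  ff.th0 = dvec(spec["th0"]);
  ff.d_i = ivec(spec["d_i"]); ff.d_j = ivec(spec["d_j"]);
  ff.d_k = ivec(spec["d_k"]); ff.d_l = ivec(spec["d_l"]);
  ff.ph0 = dvec(spec["ph0"]);
  ff.kb = as<double>(spec["kb"]); ff.ka = as<double>(spec["ka"]);
  ff.kd1 = as<double>(spec["kd1"]); ff.kd3 = as<double>(spec["kd3"]);
  ff.n_i = ivec(spec["nat_i"]); ff.n_j = ivec(spec["nat_j"]);
  ff.n_sig = dvec(spec["nat_sig"]); ff.n_eps = dvec(spec["nat_eps"]);
  ff.p_i = ivec(spec["pair_i"]); ff.p_j = ivec(spec["pair_j"]);
  ff.p_eqc = dvec(spec["pair_eqc"]); ff.p_qq = dvec(spec["pair_qq"]);
  IntegerVector ev(spec["pair_ev"]);
  ff.p_ev.assign(ev.begin(), ev.end());
  ff.lB = as<double>(spec["lB"]); ff.lambdaD = as<double>(spec["lambdaD"]);
  ff.r_qc = as<double>(spec["r_qc"]); ff.w_qc = as<double>(spec["w_qc"]);
  ff.sig_ev = as<double>(spec["sig_ev"]); ff.eps_ev = as<double>(spec["eps_ev"]);
  ff.nat_adj.assign(ff.n, {}); ff.pair_adj.assign(ff.n, {});
  ff.bond_adj.assign(ff.n, {}); ff.ang_adj.assign(ff.n, {});
  ff.dih_adj.assign(ff.n, {});
  for (size_t t = 0; t < ff.n_i.size(); ++t) {
    ff.nat_adj[ff.n_i[t]].push_back(t);
    ff.nat_adj[ff.n_j[t]].push_back(t);
  }
  for (size_t t = 0; t < ff.p_i.size(); ++t) {
    ff.pair_adj[ff.p_i[t]].push_back(t);
    ff.pair_adj[ff.p_j[t]].push_back(t);
  }
  for (size_t t = 0; t < ff.b_i.size(); ++t) {
    ff.bond_adj[ff.b_i[t]].push_back(t);
    ff.bond_adj[ff.b_j[t]].push_back(t);
  }
  for (size_t t = 0; t < ff.a_i.size(); ++t) {
    ff.ang_adj[ff.a_i[t]].push_back(t);
    ff.ang_adj[ff.a_j[t]].push_back(t);
    ff.ang_adj[ff.a_k[t]].push_back(t);
  }
  for (size_t t = 0; t < ff.d_i.size(); ++t) {
    ff.dih_adj[ff.d_i[t]].push_back(t);
    ff.dih_adj[ff.d_j[t]].push_back(t);
    ff.dih_adj[ff.d_k[t]].push_back(t);
    ff.dih_adj[ff.d_l[t]].push_back(t);
  }
  return ff;
}

// ---- pair potentials (energy and dE/dr) ----------------------------------
// Short-range divergences are continued linearly (C^1) below r_cap so that
// clashed starting configurations keep finite, bounded forces.

static inline void nat1210(double r, double sig, double eps,
                           double &e, double &dedr) {
  double rc = 0.7 * sig;
  double rr = (r < rc) ? rc : r;
  double s2 = (sig / rr) * (sig / rr);
  double s10 = s2 * s2 * s2 * s2 * s2, s12 = s10 * s2;
  e = eps * (5 * s12 - 6 * s10);
  dedr = eps * (-60 * s12 + 60 * s10) / rr;
  if (r < rc) { e += dedr * (r - rc); /* constant slope below cap */ }
}

static inline void ev12(double r, double sig, double eps,
                        double &e, double &dedr) {
  double rc = 0.7 * sig;
  double rr = (r < rc) ? rc : r;
  double s2 = (sig / rr) * (sig / rr);
  double s12 = s2 * s2 * s2 * s2 * s2 * s2;
  e = eps * s12;
  dedr = -12 * eps * s12 / rr;
  if (r < rc) e += dedr * (r - rc);
}

static inline void qcwell(double r, double eqc, double r_qc, double w,
                          double &e, double &dedr) {
  double z = (r - r_qc) / w;
  if (z > 14) { e = 0; dedr = 0; return; } // switch < 1e-6: negligible
  double sig = 1.0 / (1.0 + std::exp(z));
  e = eqc * sig;
  dedr = -eqc * sig * (1.0 - sig) / w;
}

static inline void debye(double r, double qq, double lB, double lambdaD,
                         double &e, double &dedr) {
  if (r > 8 * lambdaD) { e = 0; dedr = 0; return; } // exp(-8) tail
  const double rc = 2.0;
  double rr = (r < rc) ? rc : r;
  double ex = std::exp(-rr / lambdaD);
  e = lB * qq * ex / rr;
  dedr = -lB * qq * ex * (1.0 / (rr * rr) + 1.0 / (lambdaD * rr));
  if (r < rc) e += dedr * (r - rc);
}

// ---- geometry helpers on a flat coordinate array -------------------------

static inline void getv(const double *x, int i, double *v) {
  v[0] = x[3 * i]; v[1] = x[3 * i + 1]; v[2] = x[3 * i + 2];
}
static inline double dist3(const double *x, int i, int j, double *d) {
  d[0] = x[3 * i] - x[3 * j];
  d[1] = x[3 * i + 1] - x[3 * j + 1];
  d[2] = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
}
static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Accumulate energy (by component) and optionally forces (-dE/dx) for the
// terms listed in the given index sets; pass nullptr index sets to use all.
struct Breakdown {
  double bonded = 0, native = 0, qc = 0, elec = 0, ev = 0;
  double total() const { return bonded + native + qc + elec + ev; }
};

static void eval_terms(const double *x, const FF &ff,
                       const std::vector<int> *bonds,
                       const std::vector<int> *angs,
                       const std::vector<int> *dihs,
                       const std::vector<int> *nats,
                       const std::vector<int> *pairs,
                       Breakdown &bd, double *force) {
  double d[3];
  size_t nb = bonds ? bonds->size() : ff.b_i.size();
  for (size_t t = 0; t < nb; ++t) {
    size_t u = bonds ? (*bonds)[t] : t;
    int i = ff.b_i[u], j = ff.b_j[u];
    double r = dist3(x, i, j, d);
    double dr = r - ff.b0[u];
    bd.bonded += 0.5 * ff.kb * dr * dr;
    if (force) {
      double f = -ff.kb * dr / r;
      for (int c = 0; c < 3; ++c) {
        force[3 * i + c] += f * d[c];
        force[3 * j + c] -= f * d[c];
      }
    }
  }
  size_t na = angs ? angs->size() : ff.a_i.size();
  for (size_t t = 0; t < na; ++t) {
    size_t u = angs ? (*angs)[t] : t;
    int i = ff.a_i[u], j = ff.a_j[u], k = ff.a_k[u];
    double uvec[3], vvec[3];
    double ru = dist3(x, i, j, uvec), rv = dist3(x, k, j, vvec);
    double cth = dot3(uvec, vvec) / (ru * rv);
    if (cth > 1) cth = 1; if (cth < -1) cth = -1;
    double th = std::acos(cth);
    double dth = th - ff.th0[u];
    bd.bonded += 0.5 * ff.ka * dth * dth;
    if (force) {
      // clamp the 1/sin(theta) geometric factor near collinear geometries
      // (the harmonic angle force stays bounded; exact elsewhere)
      double sth = std::sqrt(1 - cth * cth);
      if (sth < 0.05) sth = 0.05;
      double coef = -ff.ka * dth; // = -dE/dtheta
      for (int c = 0; c < 3; ++c) {
        double gi = (cth * uvec[c] / ru - vvec[c] / rv) / (ru * sth);
        double gk = (cth * vvec[c] / rv - uvec[c] / ru) / (rv * sth);
        force[3 * i + c] += coef * gi;
        force[3 * k + c] += coef * gk;
        force[3 * j + c] -= coef * (gi + gk);
      }
    }
  }
  size_t nd = dihs ? dihs->size() : ff.d_i.size();
  for (size_t t = 0; t < nd; ++t) {
    size_t u = dihs ? (*dihs)[t] : t;
    int i = ff.d_i[u], j = ff.d_j[u], k = ff.d_k[u], l = ff.d_l[u];
    double vi[3], vj[3], vk[3], vl[3];
    getv(x, i, vi); getv(x, j, vj); getv(x, k, vk); getv(x, l, vl);
    double b1[3] = {vj[0]-vi[0], vj[1]-vi[1], vj[2]-vi[2]};
    double b2[3] = {vk[0]-vj[0], vk[1]-vj[1], vk[2]-vj[2]};
    double b3[3] = {vl[0]-vk[0], vl[1]-vk[1], vl[2]-vk[2]};
    double n1[3], n2[3];
    cross3(b1, b2, n1); cross3(b2, b3, n2);
    double nb2 = std::sqrt(dot3(b2, b2));
    double m1[3];
    cross3(n1, n2, m1);
    double phi = std::atan2(dot3(m1, b2) / nb2, dot3(n1, n2));
    double dphi = phi - ff.ph0[u];
    bd.bonded += ff.kd1 * (1 - std::cos(dphi)) + ff.kd3 * (1 - std::cos(3 * dphi));
    if (force) {
      double dEdphi = ff.kd1 * std::sin(dphi) + 3 * ff.kd3 * std::sin(3 * dphi);
      double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
      if (n1sq < 1e-4 || n2sq < 1e-4) continue; // near-collinear: no torque
      double gi[3], gl[3];
      for (int c = 0; c < 3; ++c) {
        gi[c] = -nb2 / n1sq * n1[c];
        gl[c] = nb2 / n2sq * n2[c];
      }
      double c12 = dot3(b1, b2) / (nb2 * nb2);
      double c32 = dot3(b3, b2) / (nb2 * nb2);
      for (int c = 0; c < 3; ++c) {
        double gj = -(1 + c12) * gi[c] + c32 * gl[c];
        double gk = c12 * gi[c] - (1 + c32) * gl[c];
        force[3 * i + c] -= dEdphi * gi[c];
        force[3 * j + c] -= dEdphi * gj;
        force[3 * k + c] -= dEdphi * gk;
        force[3 * l + c] -= dEdphi * gl[c];
      }
    }
  }
  size_t nn = nats ? nats->size() : ff.n_i.size();
  for (size_t t = 0; t < nn; ++t) {
    size_t u = nats ? (*nats)[t] : t;
    int i = ff.n_i[u], j = ff.n_j[u];
    double r = dist3(x, i, j, d);
    double e, dedr;
    nat1210(r, ff.n_sig[u], ff.n_eps[u], e, dedr);
    bd.native += e;
    if (force) {
      double f = -dedr / r;
      for (int c = 0; c < 3; ++c) {
        force[3 * i + c] += f * d[c];
        force[3 * j + c] -= f * d[c];
      }
    }
  }
  size_t np = pairs ? pairs->size() : ff.p_i.size();
  for (size_t t = 0; t < np; ++t) {
    size_t u = pairs ? (*pairs)[t] : t;
    int i = ff.p_i[u], j = ff.p_j[u];
    double r = dist3(x, i, j, d);
    double e, dedr, esum = 0, dsum = 0;
    if (ff.p_ev[u]) {
      ev12(r, ff.sig_ev, ff.eps_ev, e, dedr);
      bd.ev += e; esum += e; dsum += dedr;
    }
    if (ff.p_eqc[u] != 0) {
      qcwell(r, ff.p_eqc[u], ff.r_qc, ff.w_qc, e, dedr);
      bd.qc += e; dsum += dedr;
    }
    if (ff.p_qq[u] != 0) {
      debye(r, ff.p_qq[u], ff.lB, ff.lambdaD, e, dedr);
      bd.elec += e; dsum += dedr;
    }
    if (force && dsum != 0) {
      double f = -dsum / r;
      for (int c = 0; c < 3; ++c) {
        force[3 * i + c] += f * d[c];
        force[3 * j + c] -= f * d[c];
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_ff_eval(NumericMatrix coords, List spec, bool want_force) {
  FF ff = make_ff(spec);
  int n = coords.nrow();
  std::vector<double> x(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  Breakdown bd;
  eval_terms(x.data(), ff, nullptr, nullptr, nullptr, nullptr, nullptr,
             bd, want_force ? f.data() : nullptr);
  NumericMatrix force(n, 3);
  if (want_force)
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) force(i, c) = f[3 * i + c];
  return List::create(
    _["bonded"] = bd.bonded, _["native"] = bd.native,
    _["quasichemical"] = bd.qc, _["electrostatic"] = bd.elec,
    _["excluded_volume"] = bd.ev, _["total"] = bd.total(),
    _["force"] = force);
}

// ---- contact-map collective coordinate -----------------------------------

static inline double powi(double x, int n) {
  double out = 1;
  while (n > 0) {
    if (n & 1) out *= x;
    x *= x;
    n >>= 1;
  }
  return out;
}

static inline double cfun(double r, double r0, int p, int q, double *deriv) {
  double s = r / r0;
  if (s > 6) { if (deriv) *deriv = 0; return 0.0; } // C < 1e-3 tail cut
  if (std::fabs(s - 1) < 1e-4) {
    double slope = (double)p * (p - q) / (2.0 * q);
    if (deriv) *deriv = slope / r0;
    return (double)p / q + slope * (s - 1);
  }
  double sp = powi(s, p), sq = powi(s, q);
  double denom = 1 - sq;
  double c = (1 - sp) / denom;
  if (deriv) {
    double dc = (-p * sp / s * denom + q * sq / s * (1 - sp)) / (denom * denom);
    *deriv = dc / r0;
  }
  return c;
}

static double cc_eval(const double *x, const std::vector<int> &ci,
                      const std::vector<int> &cj, const std::vector<double> &cn,
                      double r0, int p, int q, double *grad) {
  double z = 0, d[3];
  for (size_t t = 0; t < ci.size(); ++t) {
    double r = dist3(x, ci[t], cj[t], d);
    double dc;
    double c = cfun(r, r0, p, q, grad ? &dc : nullptr);
    double diff = c - cn[t];
    z += diff * diff;
    if (grad) {
      double coef = 2 * diff * dc / r;
      for (int cdx = 0; cdx < 3; ++cdx) {
        grad[3 * ci[t] + cdx] += coef * d[cdx];
        grad[3 * cj[t] + cdx] -= coef * d[cdx];
      }
    }
  }
  return z;
}

// [[Rcpp::export]]
List cpp_cc(NumericMatrix coords, IntegerVector ci, IntegerVector cj,
            NumericVector cnat, double r0, int p, int q, bool want_grad) {
  int n = coords.nrow();
  std::vector<double> x(3 * n), g(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords(i, c);
  std::vector<int> vi(ci.begin(), ci.end()), vj(cj.begin(), cj.end());
  std::vector<double> vc(cnat.begin(), cnat.end());
  double z = cc_eval(x.data(), vi, vj, vc, r0, p, q,
                     want_grad ? g.data() : nullptr);
  NumericMatrix grad(n, 3);
  if (want_grad)
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) grad(i, c) = g[3 * i + c];
  return List::create(_["z"] = z, _["grad"] = grad);
}

// ---- ratchet-and-pawl overdamped Langevin --------------------------------

// [[Rcpp::export]]
List cpp_run_rmd(NumericMatrix coords0, List spec,
                 IntegerVector ci, IntegerVector cj, NumericVector cnat,
                 double r0, int p, int q,
                 double kR, double beta_tilde, double zm0,
                 int n_steps, double dt, double D, double temperature,
                 int save_stride, bool debug_check) {
  FF ff = make_ff(spec);
  int n = coords0.nrow();
  std::vector<double> x(3 * n), fphys(3 * n), gz(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords0(i, c);
  std::vector<int> vi(ci.begin(), ci.end()), vj(cj.begin(), cj.end());
  std::vector<double> vc(cnat.begin(), cnat.end());
  int n_save = n_steps / save_stride + 1;
  NumericMatrix frames(n_save, 3 * n);
  NumericVector cc_out(n_save), zm_out(n_save), ebias_out(n_save),
      epot_out(n_save);
  IntegerVector step_out(n_save);
  double zm = zm0;
  double noise = std::sqrt(2.0 * D * dt);
  double mob = D * dt / temperature;
  int isave = 0, violations = 0;
  bool aborted = false;
  RNGScope scope;
  double z = cc_eval(x.data(), vi, vj, vc, r0, p, q, nullptr);
  if (!R_finite(zm)) zm = z;
  for (int step = 0; step <= n_steps; ++step) {
    std::fill(fphys.begin(), fphys.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
    Breakdown bd;
    eval_terms(x.data(), ff, nullptr, nullptr, nullptr, nullptr, nullptr,
               bd, fphys.data());
    z = cc_eval(x.data(), vi, vj, vc, r0, p, q, gz.data());
    double ebias = 0;
    bool bias_on = z > zm && kR > 0;
    if (bias_on) {
      double pref = kR * (z - zm);
      ebias = 0.5 * kR * (z - zm) * (z - zm);
      for (int c = 0; c < 3 * n; ++c) fphys[c] -= pref * gz[c];
    }
    if (debug_check && z <= zm && bias_on) ++violations;
    if (step % save_stride == 0) {
      for (int c = 0; c < 3 * n; ++c) frames(isave, c) = x[c];
      cc_out[isave] = z; zm_out[isave] = zm;
      ebias_out[isave] = ebias; epot_out[isave] = bd.total();
      step_out[isave] = step;
      ++isave;
    }
    // ratchet reference update (Metropolis backtracking)
    if (z <= zm) zm = z;
    else if (beta_tilde <= 0 ||
             std::exp(-beta_tilde * (z - zm)) >= unif_rand()) zm = z;
    if (step == n_steps) break;
    double maxd = 0;
    for (int c = 0; c < 3 * n; ++c) {
      double dx = mob * fphys[c] + noise * norm_rand();
      if (std::fabs(dx) > maxd) maxd = std::fabs(dx);
      x[c] += dx;
    }
    if (maxd > 5.0 || !R_finite(maxd)) { aborted = true; break; }
  }
  return List::create(_["frames"] = frames, _["cc"] = cc_out,
                      _["zm"] = zm_out, _["ebias"] = ebias_out,
                      _["epot"] = epot_out, _["step"] = step_out,
                      _["n_saved"] = isave, _["zm_final"] = zm,
                      _["violations"] = violations, _["aborted"] = aborted);
}

// ---- Monte Carlo engine ---------------------------------------------------

// Collect the force-field terms touched by the moved beads.
struct Touched {
  std::vector<int> bonds, angs, dihs, nats, pairs;
};

static void collect_touched(const FF &ff, const std::vector<int> &moved,
                            std::vector<char> &mark_b, std::vector<char> &mark_a,
                            std::vector<char> &mark_d, std::vector<char> &mark_n,
                            std::vector<char> &mark_p, Touched &T) {
  T.bonds.clear(); T.angs.clear(); T.dihs.clear(); T.nats.clear(); T.pairs.clear();
  for (int b : moved) {
    for (int t : ff.bond_adj[b]) if (!mark_b[t]) { mark_b[t] = 1; T.bonds.push_back(t); }
    for (int t : ff.ang_adj[b])  if (!mark_a[t]) { mark_a[t] = 1; T.angs.push_back(t); }
    for (int t : ff.dih_adj[b])  if (!mark_d[t]) { mark_d[t] = 1; T.dihs.push_back(t); }
    for (int t : ff.nat_adj[b])  if (!mark_n[t]) { mark_n[t] = 1; T.nats.push_back(t); }
    for (int t : ff.pair_adj[b]) if (!mark_p[t]) { mark_p[t] = 1; T.pairs.push_back(t); }
  }
  for (int t : T.bonds) mark_b[t] = 0;
  for (int t : T.angs) mark_a[t] = 0;
  for (int t : T.dihs) mark_d[t] = 0;
  for (int t : T.nats) mark_n[t] = 0;
  for (int t : T.pairs) mark_p[t] = 0;
}

// Contact-map pairs touched by moved beads (for the optional rMD bias).
static void collect_cc_touched(const std::vector<std::vector<int>> &cc_adj,
                               const std::vector<int> &moved,
                               std::vector<char> &mark, std::vector<int> &out) {
  out.clear();
  for (int b : moved)
    for (int t : cc_adj[b]) if (!mark[t]) { mark[t] = 1; out.push_back(t); }
  for (int t : out) mark[t] = 0;
}

static double cc_partial(const double *x, const std::vector<int> &ci,
                         const std::vector<int> &cj, const std::vector<double> &cn,
                         double r0, int p, int q, const std::vector<int> &terms) {
  double z = 0, d[3];
  for (int t : terms) {
    double r = dist3(x, ci[t], cj[t], d);
    double diff = cfun(r, r0, p, q, nullptr) - cn[t];
    z += diff * diff;
  }
  return z;
}

static void rodrigues(double *v, const double *axis, double s, double c) {
  double k[3] = {axis[0], axis[1], axis[2]};
  double kv[3];
  cross3(k, v, kv);
  double kd = dot3(k, v);
  for (int i = 0; i < 3; ++i)
    v[i] = v[i] * c + kv[i] * s + k[i] * kd * (1 - c);
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix coords0, List spec,
                double crank_max, double cart_max, bool pivot_enabled,
                double target_acc, bool tune, int burn_in,
                int n_moves, double temperature, int save_stride,
                bool bias_on,
                IntegerVector ci, IntegerVector cj, NumericVector cnat,
                double r0, int p, int q,
                double kR, double beta_tilde, double zm0) {
  FF ff = make_ff(spec);
  int n = coords0.nrow();
  std::vector<double> x(3 * n), xold(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = coords0(i, c);
  std::vector<int> vi(ci.begin(), ci.end()), vj(cj.begin(), cj.end());
  std::vector<double> vc(cnat.begin(), cnat.end());
  std::vector<std::vector<int>> cc_adj(n);
  for (size_t t = 0; t < vi.size(); ++t) {
    cc_adj[vi[t]].push_back(t);
    cc_adj[vj[t]].push_back(t);
  }
  std::vector<char> mark_b(ff.b_i.size(), 0), mark_a(ff.a_i.size(), 0),
      mark_d(ff.d_i.size(), 0), mark_n(ff.n_i.size(), 0),
      mark_p(ff.p_i.size(), 0), mark_cc(vi.size(), 0);
  Touched T;
  std::vector<int> moved, cc_terms;
  int n_save = n_moves / save_stride + 1;
  NumericMatrix frames(n_save, 3 * n);
  NumericVector epot_out(n_save), cc_out(n_save), zm_out(n_save);
  IntegerVector step_out(n_save);
  RNGScope scope;
  double beta = 1.0 / temperature;
  double zm = zm0, z = NA_REAL;
  if (bias_on) {
    z = cc_eval(x.data(), vi, vj, vc, r0, p, q, nullptr);
    if (!R_finite(zm)) zm = z;
  }
  Breakdown bd0;
  eval_terms(x.data(), ff, nullptr, nullptr, nullptr, nullptr, nullptr, bd0, nullptr);
  double epot = bd0.total();
  int isave = 0;
  long acc_crank = 0, try_crank = 0, acc_cart = 0, try_cart = 0,
       acc_piv = 0, try_piv = 0;
  long accepted = 0;
  double p_pivot = pivot_enabled ? 0.1 : 0.0;
  int tune_window = 200;
  long w_try_crank = 0, w_acc_crank = 0, w_try_cart = 0, w_acc_cart = 0;
  for (int mv = 0; mv <= n_moves; ++mv) {
    if (mv % save_stride == 0) {
      for (int c = 0; c < 3 * n; ++c) frames(isave, c) = x[c];
      epot_out[isave] = epot;
      cc_out[isave] = bias_on ? z : NA_REAL;
      zm_out[isave] = bias_on ? zm : NA_REAL;
      step_out[isave] = mv;
      ++isave;
    }
    if (mv == n_moves) break;
    double u = unif_rand();
    moved.clear();
    int movetype; // 0 crank, 1 cart, 2 pivot
    if (u < p_pivot) movetype = 2;
    else movetype = (unif_rand() < 0.5) ? 0 : 1;
    if (movetype == 0 && n < 4) movetype = 1;
    if (movetype == 0) {
      int gap = 2 + (int)(unif_rand() * 5); // 2..6
      if (gap > n - 1) gap = n - 1;
      int i0 = (int)(unif_rand() * (n - gap));
      int i1 = i0 + gap;
      double axis[3];
      double r = dist3(x.data(), i1, i0, axis);
      if (r < 1e-9) continue;
      for (int c = 0; c < 3; ++c) axis[c] /= r;
      double ang = (2 * unif_rand() - 1) * crank_max;
      double s = std::sin(ang), cg = std::cos(ang);
      for (int b = i0 + 1; b < i1; ++b) moved.push_back(b);
      if (moved.empty()) continue;
      ++try_crank; ++w_try_crank;
      for (int b : moved)
        for (int c = 0; c < 3; ++c) xold[3 * b + c] = x[3 * b + c];
      double org[3] = {x[3 * i0], x[3 * i0 + 1], x[3 * i0 + 2]};
      for (int b : moved) {
        double v[3] = {x[3 * b] - org[0], x[3 * b + 1] - org[1], x[3 * b + 2] - org[2]};
        rodrigues(v, axis, s, cg);
        for (int c = 0; c < 3; ++c) x[3 * b + c] = org[c] + v[c];
      }
    } else if (movetype == 1) {
      int b = (int)(unif_rand() * n);
      moved.push_back(b);
      ++try_cart; ++w_try_cart;
      for (int c = 0; c < 3; ++c) {
        xold[3 * b + c] = x[3 * b + c];
        x[3 * b + c] += (2 * unif_rand() - 1) * cart_max;
      }
    } else {
      int piv = 1 + (int)(unif_rand() * (n - 2)); // 1..n-2
      bool tail = unif_rand() < 0.5;
      double axis[3];
      do {
        axis[0] = norm_rand(); axis[1] = norm_rand(); axis[2] = norm_rand();
      } while (dot3(axis, axis) < 1e-12);
      double an = std::sqrt(dot3(axis, axis));
      for (int c = 0; c < 3; ++c) axis[c] /= an;
      double ang = (2 * unif_rand() - 1) * M_PI;
      double s = std::sin(ang), cg = std::cos(ang);
      if (tail) for (int b = piv + 1; b < n; ++b) moved.push_back(b);
      else for (int b = 0; b < piv; ++b) moved.push_back(b);
      if (moved.empty()) continue;
      ++try_piv;
      double org[3] = {x[3 * piv], x[3 * piv + 1], x[3 * piv + 2]};
      for (int b : moved) {
        for (int c = 0; c < 3; ++c) xold[3 * b + c] = x[3 * b + c];
        double v[3] = {x[3 * b] - org[0], x[3 * b + 1] - org[1], x[3 * b + 2] - org[2]};
        rodrigues(v, axis, s, cg);
        for (int c = 0; c < 3; ++c) x[3 * b + c] = org[c] + v[c];
      }
    }
    // delta energy over touched terms
    collect_touched(ff, moved, mark_b, mark_a, mark_d, mark_n, mark_p, T);
    Breakdown bnew, bold;
    eval_terms(x.data(), ff, &T.bonds, &T.angs, &T.dihs, &T.nats, &T.pairs,
               bnew, nullptr);
    // swap to old positions
    for (int b : moved)
      for (int c = 0; c < 3; ++c) std::swap(x[3 * b + c], xold[3 * b + c]);
    eval_terms(x.data(), ff, &T.bonds, &T.angs, &T.dihs, &T.nats, &T.pairs,
               bold, nullptr);
    double dE = bnew.total() - bold.total();
    double znew = z, dbias = 0;
    if (bias_on) {
      collect_cc_touched(cc_adj, moved, mark_cc, cc_terms);
      double zpart_old = cc_partial(x.data(), vi, vj, vc, r0, p, q, cc_terms);
      // swap back to new positions to compute new partial
      for (int b : moved)
        for (int c = 0; c < 3; ++c) std::swap(x[3 * b + c], xold[3 * b + c]);
      double zpart_new = cc_partial(x.data(), vi, vj, vc, r0, p, q, cc_terms);
      znew = z + (zpart_new - zpart_old);
      double bias_old = (z > zm) ? 0.5 * kR * (z - zm) * (z - zm) : 0.0;
      double bias_new = (znew > zm) ? 0.5 * kR * (znew - zm) * (znew - zm) : 0.0;
      dbias = bias_new - bias_old;
      // leave x at the NEW positions (same state as when !bias_on? no:)
      // for the !bias_on branch x currently holds OLD positions
    } else {
      // restore new positions for the acceptance outcome handling below
      for (int b : moved)
        for (int c = 0; c < 3; ++c) std::swap(x[3 * b + c], xold[3 * b + c]);
    }
    bool accept = (dE + dbias <= 0) ||
                  (std::exp(-beta * (dE + dbias)) >= unif_rand());
    if (accept) {
      epot += dE;
      ++accepted;
      if (movetype == 0) { ++acc_crank; ++w_acc_crank; }
      else if (movetype == 1) { ++acc_cart; ++w_acc_cart; }
      else ++acc_piv;
      if (bias_on) {
        z = znew;
        if (z <= zm) zm = z;
        else if (beta_tilde <= 0 ||
                 std::exp(-beta_tilde * (z - zm)) >= unif_rand()) zm = z;
      }
    } else {
      // reject: restore old positions
      for (int b : moved)
        for (int c = 0; c < 3; ++c) x[3 * b + c] = xold[3 * b + c];
    }
    // boldness auto-tuning during burn-in
    if (tune && mv < burn_in) {
      if (w_try_crank >= tune_window) {
        double a = (double)w_acc_crank / w_try_crank;
        crank_max *= std::exp(0.5 * (a - target_acc));
        if (crank_max > M_PI) crank_max = M_PI;
        if (crank_max < 1e-4) crank_max = 1e-4;
        w_try_crank = 0; w_acc_crank = 0;
      }
      if (w_try_cart >= tune_window) {
        double a = (double)w_acc_cart / w_try_cart;
        cart_max *= std::exp(0.5 * (a - target_acc));
        if (cart_max > 5.0) cart_max = 5.0;
        if (cart_max < 1e-4) cart_max = 1e-4;
        w_try_cart = 0; w_acc_cart = 0;
      }
    }
  }
  return List::create(
      _["frames"] = frames, _["epot"] = epot_out, _["cc"] = cc_out,
      _["zm"] = zm_out, _["step"] = step_out,
      _["acc_crank"] = try_crank ? (double)acc_crank / try_crank : NA_REAL,
      _["acc_cart"] = try_cart ? (double)acc_cart / try_cart : NA_REAL,
      _["acc_pivot"] = try_piv ? (double)acc_piv / try_piv : NA_REAL,
      _["acc_total"] = (double)accepted / n_moves,
      _["crank_max"] = crank_max, _["cart_max"] = cart_max,
      _["zm_final"] = zm);
}

// ---- Onsager-Machlup path log-weight --------------------------------------

// log w = - sum_steps sum_coords (dx - (D dt / T) F)^2 / (4 D dt),
// with the unbiased force evaluated at the step's starting frame (Ito).
// [[Rcpp::export]]
double cpp_path_logweight(NumericMatrix frames, List spec, double D,
                          double dt, double temperature) {
  FF ff = make_ff(spec);
  int nf = frames.nrow();
  int n3 = frames.ncol();
  std::vector<double> x(n3), f(n3);
  double lw = 0;
  double mob = D * dt / temperature;
  for (int k = 0; k < nf - 1; ++k) {
    for (int c = 0; c < n3; ++c) x[c] = frames(k, c);
    std::fill(f.begin(), f.end(), 0.0);
    Breakdown bd;
    eval_terms(x.data(), ff, nullptr, nullptr, nullptr, nullptr, nullptr,
               bd, f.data());
    for (int c = 0; c < n3; ++c) {
      double dev = frames(k + 1, c) - frames(k, c) - mob * f[c];
      lw -= dev * dev / (4 * D * dt);
    }
  }
  return lw;
}
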