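#include "rodsim.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Inextensibility: one equality constraint per segment, C_i = |e_i| - l0,
// linearized at predicted positions x + dt v. The Schur system
// A = J M^-1 J^T is symmetric tridiagonal:
//   diag_i = invm_i + invm_{i+1}
//   off_i  = -invm_{i+1} (d_i . d_{i+1})
// and is solved exactly (Thomas algorithm) in global mode, or by local
// Gauss-Seidel / Jacobi sweeps over individual constraints.
// ---------------------------------------------------------------------------

struct DistSys {
  int nseg;
  std::vector<Vec3> d;            // unit segment directions (at prediction)
  std::vector<double> diag, off;  // A (off_i couples i and i+1)
  std::vector<double> C0;         // start-of-step position violation
  double dt, stab;
};

// The distance phase solves, per iteration, the Newton step of
//   C(x + dt v) = (1 - stab) * C(x)
// i.e. the corrected velocities carry each segment to (1 - stab) of its
// pre-step violation by the end of the step. stab = 0 reduces to zeroing
// the violation rate at the linearization point; stab = 1 to full
// position projection. Re-linearizing across iterations makes the
// iteration count govern how exactly the nonlinear chain is satisfied.
static DistSys assembleDist(const Rod& rod, double dt, double stab,
                            bool predicted) {
  DistSys s;
  s.dt = dt; s.stab = stab;
  s.nseg = rod.active - 1;
  s.d.resize(s.nseg); s.C0.resize(s.nseg);
  s.diag.resize(s.nseg); s.off.assign(std::max(s.nseg - 1, 0), 0.0);
  for (int i = 0; i < s.nseg; ++i) {
    Vec3 e0 = rod.r[i + 1] - rod.r[i];
    double len0 = norm(e0);
    Vec3 e = predicted ? e0 + dt * (rod.v[i + 1] - rod.v[i]) : e0;
    double len = norm(e);
    if (len <= 1e-12 || len0 <= 1e-12)
      stop("degenerate zero-length segment at %d", i + 1);
    s.d[i] = (1.0 / len) * e;
    s.C0[i] = len0 - rod.l0;
    s.diag[i] = rod.invm[i] + rod.invm[i + 1];
  }
  for (int i = 0; i + 1 < s.nseg; ++i)
    s.off[i] = -rod.invm[i + 1] * dot(s.d[i], s.d[i + 1]);
  return s;
}

// predicted end-of-step violation of segment i under current velocities
static inline double cpred(const Rod& rod, const DistSys& s, int i) {
  Vec3 e = (rod.r[i + 1] + s.dt * rod.v[i + 1]) - (rod.r[i] + s.dt * rod.v[i]);
  return norm(e) - rod.l0;
}

// predicted end-of-step violation including pseudo-velocities
static inline double cpredPs(const Rod& rod, const DistSys& s, int i,
                             const std::vector<Vec3>* vp) {
  Vec3 u1 = rod.v[i + 1], u0 = rod.v[i];
  if (vp) { u1 = u1 + (*vp)[i + 1]; u0 = u0 + (*vp)[i]; }
  Vec3 e = (rod.r[i + 1] + s.dt * u1) - (rod.r[i] + s.dt * u0);
  return norm(e) - rod.l0;
}

// Newton residual of segment i (units of a velocity)
static inline double cresid(const Rod& rod, const DistSys& s, int i) {
  return (cpred(rod, s, i) - (1.0 - s.stab) * s.C0[i]) / s.dt;
}

static void applyImpulse(Rod& rod, const DistSys& s, int i, double lam) {
  rod.v[i] = rod.v[i] - (rod.invm[i] * lam) * s.d[i];
  rod.v[i + 1] = rod.v[i + 1] + (rod.invm[i + 1] * lam) * s.d[i];
}

// exact tridiagonal solve of A lam = rhs; rows with zero diagonal (both
// endpoints fixed) are decoupled with lam = 0
static std::vector<double> thomasSolve(const DistSys& s,
                                       const std::vector<double>& rhs) {
  int n = s.nseg;
  std::vector<double> a(n), b(n), c(n), r(rhs), lam(n, 0.0);
  for (int i = 0; i < n; ++i) {
    b[i] = s.diag[i];
    a[i] = (i > 0) ? s.off[i - 1] : 0.0;
    c[i] = (i + 1 < n) ? s.off[i] : 0.0;
    if (b[i] <= 1e-300) { b[i] = 1.0; a[i] = c[i] = 0.0; r[i] = 0.0; }
  }
  // forward elimination
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    r[i] -= m * r[i - 1];
  }
  lam[n - 1] = r[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    lam[i] = (r[i] - c[i] * lam[i + 1]) / b[i];
  return lam;
}

static double residualRms(const Rod& rod, const DistSys& s) {
  double acc = 0;
  for (int i = 0; i < s.nseg; ++i) {
    double res = cresid(rod, s, i);
    acc += res * res;
  }
  return std::sqrt(acc / s.nseg);
}

void distancePhase(Rod& rod, const SimConfig& cfg, double dt,
                   std::vector<double>* residuals,
                   std::vector<Vec3>* vpseudo) {
  if (rod.active < 2 || cfg.distance_mode == 3) return;
  DistSys s = assembleDist(rod, dt, cfg.stabilization_distance, true);
  if (cfg.distance_mode == 0) {
    // split solve: (a) momentum-carrying impulses zero the violation
    // rates; (b) the positional Newton correction goes to the
    // pseudo-velocities (position update only), so jammed configurations
    // are projected without pumping momentum
    std::vector<double> rhs(s.nseg);
    if (vpseudo) {
      for (int i = 0; i < s.nseg; ++i)
        rhs[i] = -dot(s.d[i], rod.v[i + 1] - rod.v[i]);
      std::vector<double> lam = thomasSolve(s, rhs);
      for (int i = 0; i < s.nseg; ++i) applyImpulse(rod, s, i, lam[i]);
      for (int i = 0; i < s.nseg; ++i)
        rhs[i] = -(cpredPs(rod, s, i, vpseudo) -
                   (1.0 - s.stab) * s.C0[i]) / dt;
      std::vector<double> lam2 = thomasSolve(s, rhs);
      for (int i = 0; i < s.nseg; ++i) {
        (*vpseudo)[i] = (*vpseudo)[i] - (rod.invm[i] * lam2[i]) * s.d[i];
        (*vpseudo)[i + 1] = (*vpseudo)[i + 1] + (rod.invm[i + 1] * lam2[i]) * s.d[i];
      }
    } else {
      // one-shot semantics: a single combined solve of the assembled
      // system (exactly the dense solve of J M^-1 J^T)
      for (int i = 0; i < s.nseg; ++i) rhs[i] = -cresid(rod, s, i);
      std::vector<double> lam = thomasSolve(s, rhs);
      for (int i = 0; i < s.nseg; ++i) applyImpulse(rod, s, i, lam[i]);
    }
    if (residuals) residuals->push_back(residualRms(rod, s));
  } else {
    // local sweeps on the linearized system: residuals are tracked
    // through the tridiagonal coefficients, so the iteration is classical
    // Gauss-Seidel / Jacobi on A lambda = -r0 with its textbook
    // convergence behaviour
    bool jacobi = (cfg.distance_mode == 2);
    std::vector<double> r(s.nseg), dl(s.nseg);
    for (int i = 0; i < s.nseg; ++i) r[i] = cresid(rod, s, i);
    auto apply = [&](int i, double lam) {
      applyImpulse(rod, s, i, lam);
      r[i] += s.diag[i] * lam;
      if (i > 0) r[i - 1] += s.off[i - 1] * lam;
      if (i + 1 < s.nseg) r[i + 1] += s.off[i] * lam;
    };
    for (int sweep = 0; sweep < cfg.distance_iterations; ++sweep) {
      if (jacobi) {
        for (int i = 0; i < s.nseg; ++i) {
          double d = s.diag[i];
          dl[i] = (d > 1e-300) ? -r[i] / d : 0.0;
        }
        for (int i = 0; i < s.nseg; ++i) apply(i, dl[i]);
      } else {
        for (int i = 0; i < s.nseg; ++i) {
          double d = s.diag[i];
          if (d <= 1e-300) continue;
          apply(i, -r[i] / d);
        }
      }
      if (residuals) {
        double acc = 0;
        for (int i = 0; i < s.nseg; ++i) acc += r[i] * r[i];
        residuals->push_back(std::sqrt(acc / s.nseg));
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Concentric constraints: every dynamic guidewire point that lies alongside
// the catheter is linked to its nearest catheter segment; impulses act
// perpendicular to the catheter tangent only (coaxial sliding is free) and
// are split between the two segment endpoints with weights (1-w, w).
// ---------------------------------------------------------------------------

void concentricPhase(Rod& gw, Rod& cath, const SimConfig& cfg, double dt) {
  int nc = cath.active - 1;
  if (nc < 1) return;
  for (int i = 0; i < gw.active; ++i) {
    if (gw.invm[i] <= 0) continue;
    Vec3 p = gw.r[i] + dt * gw.v[i];
    int best = -1; double bestw = 0, bestd2 = std::numeric_limits<double>::max();
    bool beyond_tip = false;
    for (int j = 0; j < nc; ++j) {
      Vec3 a = cath.r[j] + dt * cath.v[j];
      Vec3 bb = cath.r[j + 1] + dt * cath.v[j + 1];
      Vec3 ab = bb - a;
      double L2 = dot(ab, ab);
      double wraw = (L2 > 0) ? dot(p - a, ab) / L2 : 0.0;
      double w = std::min(1.0, std::max(0.0, wraw));
      Vec3 cpt = a + w * ab;
      double d2 = dot(p - cpt, p - cpt);
      if (d2 < bestd2) { bestd2 = d2; best = j; bestw = w; beyond_tip = (j == 0 && wraw < 0); }
    }
    if (best < 0 || beyond_tip) continue; // point past the catheter tip: free
    int j = best; double w = bestw;
    Vec3 a = cath.r[j] + dt * cath.v[j];
    Vec3 bb = cath.r[j + 1] + dt * cath.v[j + 1];
    Vec3 t = normalize(bb - a);
    Vec3 cpt = a + w * (bb - a);
    Vec3 off = p - cpt;
    Vec3 offp = off - dot(off, t) * t;
    Vec3 u = gw.v[i] - ((1 - w) * cath.v[j] + w * cath.v[j + 1]);
    Vec3 up = u - dot(u, t) * t;
    double keff = gw.invm[i] + (1 - w) * (1 - w) * cath.invm[j] + w * w * cath.invm[j + 1];
    if (keff <= 0) continue;
    Vec3 target = up + (cfg.stabilization / dt) * offp;
    Vec3 P = (-1.0 / keff) * target;
    gw.v[i] = gw.v[i] + gw.invm[i] * P;
    cath.v[j] = cath.v[j] - ((1 - w) * cath.invm[j]) * P;
    cath.v[j + 1] = cath.v[j + 1] - (w * cath.invm[j + 1]) * P;
  }
}

// ---------------------------------------------------------------------------
// Contact resolution: projected Gauss-Seidel over contacts; non-negative
// accumulated normal impulses with Baumgarte depth stabilization, friction
// clamped to the Coulomb cone |j_t| <= mu j_n.
//
// Split impulses: the depth-stabilization share of the normal impulse is
// accumulated on a pseudo-velocity (vpseudo) that advances positions at
// the end of the step but carries no momentum, so resting contacts do not
// bounce. When the caller passes no pseudo-velocity array the bias is
// applied to the real velocities (one-shot resolution semantics).
// ---------------------------------------------------------------------------

void contactPhase(Rod& rod, ContactSet& cs, const SimConfig& cfg, double dt,
                  std::vector<Vec3>* vpseudo) {
  int nc = cs.point.size();
  cs.jn.assign(nc, 0.0);
  std::vector<double> jb(nc, 0.0);
  std::vector<Vec3> jt(nc, Vec3());
  for (int iter = 0; iter < cfg.contact_iterations; ++iter) {
    for (int c = 0; c < nc; ++c) {
      int p = cs.point[c];
      if (rod.invm[p] <= 0) continue;
      double m = rod.mass[p];
      const Vec3& n = cs.normal[c];
      // momentum-carrying impulse: remove approaching normal velocity
      double vn = dot(rod.v[p], n);
      double dj = m * (0.0 - vn);
      double jn_new = std::max(0.0, cs.jn[c] + dj);
      dj = jn_new - cs.jn[c];
      cs.jn[c] = jn_new;
      rod.v[p] = rod.v[p] + (rod.invm[p] * dj) * n;
      // position-stabilization impulse on the pseudo-velocity
      Vec3& vps = vpseudo ? (*vpseudo)[p] : rod.v[p];
      double target = cfg.stabilization * cs.depth[c] / dt;
      double vbn = vpseudo ? dot(vps, n) : dot(rod.v[p], n);
      double db = m * (target - vbn);
      double jb_new = std::max(0.0, jb[c] + db);
      db = jb_new - jb[c];
      jb[c] = jb_new;
      vps = vps + (rod.invm[p] * db) * n;
      // friction against the full normal load
      Vec3 vt = rod.v[p] - dot(rod.v[p], n) * n;
      Vec3 jt_new = jt[c] - m * vt;
      double jmax = cs.mu[c] * (cs.jn[c] + jb[c]);
      double jtn = norm(jt_new);
      if (jtn > jmax) jt_new = (jmax / jtn) * jt_new;
      Vec3 djt = jt_new - jt[c];
      jt[c] = jt_new;
      rod.v[p] = rod.v[p] + rod.invm[p] * djt;
    }
  }
  cs.jt.resize(nc);
  for (int c = 0; c < nc; ++c) {
    cs.jt[c] = norm(jt[c]);
    cs.jn[c] += jb[c]; // report the total normal load
  }
}

// ---------------------------------------------------------------------------
// Exports
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_assemble_distance(List rod, double dt, double stabilization,
                           bool predicted = true) {
  Rod R = rodFromList(rod);
  DistSys s = assembleDist(R, dt, stabilization, predicted);
  NumericMatrix D(s.nseg, 3);
  NumericVector diag(s.nseg), off(std::max(s.nseg - 1, 0)), C(s.nseg),
                rate(s.nseg), rhs(s.nseg);
  for (int i = 0; i < s.nseg; ++i) {
    D(i, 0) = s.d[i].x; D(i, 1) = s.d[i].y; D(i, 2) = s.d[i].z;
    diag[i] = s.diag[i]; C[i] = s.C0[i];
    rate[i] = dot(s.d[i], R.v[i + 1] - R.v[i]);
    rhs[i] = -cresid(R, s, i);
  }
  for (int i = 0; i + 1 < s.nseg; ++i) off[i] = s.off[i];
  return List::create(_["diagonal"] = diag, _["off_diagonal"] = off,
                      _["directions"] = D, _["violation"] = C,
                      _["violation_rate"] = rate, _["rhs"] = rhs);
}

// [[Rcpp::export]]
List cpp_solve_distance_global(List rod, double dt, double stabilization) {
  Rod R = rodFromList(rod);
  std::vector<Vec3> v0 = R.v;
  SimConfig cfg; cfg.distance_mode = 0; cfg.stabilization = stabilization;
  cfg.distance_iterations = 1;
  distancePhase(R, cfg, dt, nullptr);
  NumericMatrix imp(R.n, 3);
  for (int i = 0; i < R.n; ++i) {
    Vec3 dP = R.mass[i] * (R.v[i] - v0[i]);
    if (R.invm[i] <= 0) dP = Vec3();
    imp(i, 0) = dP.x; imp(i, 1) = dP.y; imp(i, 2) = dP.z;
  }
  return List::create(_["rod"] = rodToList(R), _["impulses"] = imp);
}

// [[Rcpp::export]]
List cpp_iterate_distance_local(List rod, std::string mode, int iterations,
                                double dt, double stabilization) {
  Rod R = rodFromList(rod);
  std::vector<Vec3> v0 = R.v;
  SimConfig cfg;
  cfg.distance_mode = (mode == "jacobi") ? 2 : 1;
  cfg.stabilization = stabilization;
  cfg.distance_iterations = iterations;
  std::vector<double> res;
  distancePhase(R, cfg, dt, &res);
  NumericMatrix imp(R.n, 3);
  for (int i = 0; i < R.n; ++i) {
    Vec3 dP = R.mass[i] * (R.v[i] - v0[i]);
    if (R.invm[i] <= 0) dP = Vec3();
    imp(i, 0) = dP.x; imp(i, 1) = dP.y; imp(i, 2) = dP.z;
  }
  return List::create(_["rod"] = rodToList(R), _["impulses"] = imp,
                      _["residuals"] = NumericVector(res.begin(), res.end()));
}

// [[Rcpp::export]]
List cpp_concentric_constraints(List guidewire, List catheter, double dt,
                                double stabilization) {
  Rod G = rodFromList(guidewire), C = rodFromList(catheter);
  std::vector<Vec3> gv0 = G.v, cv0 = C.v;
  SimConfig cfg; cfg.stabilization = stabilization;
  concentricPhase(G, C, cfg, dt);
  NumericMatrix gi(G.n, 3), ci(C.n, 3);
  for (int i = 0; i < G.n; ++i) {
    Vec3 dP = (G.invm[i] > 0) ? G.mass[i] * (G.v[i] - gv0[i]) : Vec3();
    gi(i, 0) = dP.x; gi(i, 1) = dP.y; gi(i, 2) = dP.z;
  }
  for (int i = 0; i < C.n; ++i) {
    Vec3 dP = (C.invm[i] > 0) ? C.mass[i] * (C.v[i] - cv0[i]) : Vec3();
    ci(i, 0) = dP.x; ci(i, 1) = dP.y; ci(i, 2) = dP.z;
  }
  return List::create(_["guidewire"] = rodToList(G), _["catheter"] = rodToList(C),
                      _["guidewire_impulses"] = gi, _["catheter_impulses"] = ci);
}

// [[Rcpp::export]]
List cpp_resolve_contacts(List rod, IntegerVector point, NumericMatrix normal,
                          NumericVector depth, NumericVector mu, double dt,
                          double stabilization, int iterations) {
  Rod R = rodFromList(rod);
  ContactSet cs;
  for (int c = 0; c < point.size(); ++c) {
    cs.point.push_back(point[c] - 1);
    cs.normal.push_back(Vec3(normal(c, 0), normal(c, 1), normal(c, 2)));
    cs.depth.push_back(depth[c]);
    cs.mu.push_back(mu[c]);
  }
  SimConfig cfg; cfg.stabilization = stabilization;
  cfg.contact_iterations = iterations;
  contactPhase(R, cs, cfg, dt);
  return List::create(_["rod"] = rodToList(R),
                      _["normal_impulse"] = NumericVector(cs.jn.begin(), cs.jn.end()),
                      _["tangential_impulse"] = NumericVector(cs.jt.begin(), cs.jt.end()));
}
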