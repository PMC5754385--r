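#include "rodsim.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// List <-> struct conversion
// ---------------------------------------------------------------------------

Rod rodFromList(const List& rod) {
  Rod out;
  NumericMatrix P = rod["points"], Vm = rod["velocities"];
  NumericMatrix Q = rod["frames"], W = rod["angular_velocities"];
  NumericVector mass = rod["mass"], invm = rod["inv_mass"];
  out.n = P.nrow();
  out.active = as<int>(rod["active_count"]);
  out.l0 = as<double>(rod["rest_segment_length"]);
  out.s = as<double>(rod["inserted_length"]);
  out.r.resize(out.n); out.v.resize(out.n);
  out.mass.resize(out.n); out.invm.resize(out.n);
  for (int i = 0; i < out.n; ++i) {
    out.r[i] = Vec3(P(i, 0), P(i, 1), P(i, 2));
    out.v[i] = Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    out.mass[i] = mass[i];
    out.invm[i] = invm[i];
  }
  int ne = out.n - 1;
  out.q.resize(ne); out.w.resize(ne);
  for (int j = 0; j < ne; ++j) {
    out.q[j] = Quat(Q(j, 0), Q(j, 1), Q(j, 2), Q(j, 3));
    out.w[j] = Vec3(W(j, 0), W(j, 1), W(j, 2));
  }
  out.rest_darboux.assign(std::max(out.n - 2, 0), Vec3());
  if (rod.containsElementNamed("rest_darboux") && !Rf_isNull(rod["rest_darboux"])) {
    NumericMatrix D = rod["rest_darboux"];
    for (int k = 0; k < D.nrow() && k < out.n - 2; ++k)
      out.rest_darboux[k] = Vec3(D(k, 0), D(k, 1), D(k, 2));
  }
  NumericVector e = rod["entry"], a = rod["axis"];
  out.entry = Vec3(e[0], e[1], e[2]);
  out.axis = Vec3(a[0], a[1], a[2]);
  out.twist_angle = as<double>(rod["twist_angle"]);
  return out;
}

List rodToList(const Rod& rod) {
  int n = rod.n, ne = n - 1;
  NumericMatrix P(n, 3), Vm(n, 3), Q(ne, 4), W(ne, 3);
  NumericVector mass(n), invm(n);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = rod.r[i].x; P(i, 1) = rod.r[i].y; P(i, 2) = rod.r[i].z;
    Vm(i, 0) = rod.v[i].x; Vm(i, 1) = rod.v[i].y; Vm(i, 2) = rod.v[i].z;
    mass[i] = rod.mass[i]; invm[i] = rod.invm[i];
  }
  for (int j = 0; j < ne; ++j) {
    Q(j, 0) = rod.q[j].w; Q(j, 1) = rod.q[j].x; Q(j, 2) = rod.q[j].y; Q(j, 3) = rod.q[j].z;
    W(j, 0) = rod.w[j].x; W(j, 1) = rod.w[j].y; W(j, 2) = rod.w[j].z;
  }
  NumericMatrix D(std::max(n - 2, 0), 3);
  for (int k = 0; k < (int)rod.rest_darboux.size(); ++k) {
    D(k, 0) = rod.rest_darboux[k].x; D(k, 1) = rod.rest_darboux[k].y; D(k, 2) = rod.rest_darboux[k].z;
  }
  return List::create(
    _["points"] = P, _["velocities"] = Vm, _["frames"] = Q,
    _["angular_velocities"] = W, _["mass"] = mass, _["inv_mass"] = invm,
    _["rest_segment_length"] = rod.l0, _["inserted_length"] = rod.s,
    _["active_count"] = rod.active, _["rest_darboux"] = D,
    _["entry"] = NumericVector::create(rod.entry.x, rod.entry.y, rod.entry.z),
    _["axis"] = NumericVector::create(rod.axis.x, rod.axis.y, rod.axis.z),
    _["twist_angle"] = rod.twist_angle);
}

Params paramsFromList(const List& p) {
  Params out;
  out.Eb = as<double>(p["young_modulus_shaft"]);
  out.nu = p.containsElementNamed("poisson_ratio") ? as<double>(p["poisson_ratio"]) : 0.3;
  out.twist_stiffening = p.containsElementNamed("twist_stiffening") ? as<double>(p["twist_stiffening"]) : 10.0;
  out.radius = as<double>(p["radius"]);
  out.rho = as<double>(p["density"]);
  out.Kp = as<double>(p["parallel_spring_constant"]);
  out.alpha = as<double>(p["tip_modulus_ratio"]);
  out.tip_points = as<int>(p["tip_point_count"]);
  out.mu = as<double>(p["friction_coefficient"]);
  return out;
}

SimConfig configFromList(const List& c) {
  SimConfig out;
  out.dt = as<double>(c["dt"]);
  out.damping = as<double>(c["damping"]);
  NumericVector g = c["gravity"];
  out.gravity = Vec3(g[0], g[1], g[2]);
  out.stabilization = as<double>(c["stabilization"]);
  out.stabilization_distance = c.containsElementNamed("stabilization_distance") ?
    as<double>(c["stabilization_distance"]) : 1.0;
  out.distance_mode = as<int>(c["distance_mode"]);
  out.distance_iterations = as<int>(c["distance_iterations"]);
  out.outer_iterations = as<int>(c["outer_iterations"]);
  out.contact_iterations = as<int>(c["contact_iterations"]);
  out.penalty_stiffness = as<double>(c["penalty_stiffness"]);
  out.inertia_safety = c.containsElementNamed("inertia_safety") ? as<double>(c["inertia_safety"]) : 4.0;
  return out;
}

// ---------------------------------------------------------------------------
// Elastic model.
//
// Bend/twist: for each inner joint k between edges k and k+1 the discrete
// Darboux vector is Omega = (2/l0) * Im(conj(q_k) * q_{k+1}) (body frame of
// edge k), and E = (l0/2) * sum_c B_c (Omega_c - Omega0_c)^2 with
// B_1 = B_2 = E I (bending) and B_3 = G J (twist).
//
// Parallel constraint: per edge, E = (Kp l0 / 2) |d3(q) - e/|e||^2, the CoRdE
// penalty coupling frames to the centreline; its negative gradient yields
// forces on both endpoints and a torque on the frame.
// ---------------------------------------------------------------------------

// is edge j dynamic (both endpoints movable)?
static inline bool edgeDynamic(const Rod& rod, int j) {
  return rod.invm[j] > 0 && rod.invm[j + 1] > 0;
}

// P = conj(a) * b, imaginary part and its partials w.r.t. a and b
static inline void relRotIm(const Quat& a, const Quat& b, double P[3],
                            double dPa[3][4], double dPb[3][4]) {
  P[0] = a.w * b.x - a.x * b.w - a.y * b.z + a.z * b.y;
  P[1] = a.w * b.y + a.x * b.z - a.y * b.w - a.z * b.x;
  P[2] = a.w * b.z - a.x * b.y + a.y * b.x - a.z * b.w;
  double da0[4] = { b.x, -b.w, -b.z,  b.y };
  double da1[4] = { b.y,  b.z, -b.w, -b.x };
  double da2[4] = { b.z, -b.y,  b.x, -b.w };
  double db0[4] = { -a.x,  a.w,  a.z, -a.y };
  double db1[4] = { -a.y, -a.z,  a.w,  a.x };
  double db2[4] = { -a.z,  a.y, -a.x,  a.w };
  for (int i = 0; i < 4; ++i) {
    dPa[0][i] = da0[i]; dPa[1][i] = da1[i]; dPa[2][i] = da2[i];
    dPb[0][i] = db0[i]; dPb[1][i] = db1[i]; dPb[2][i] = db2[i];
  }
}

// torque (world) from an energy gradient w.r.t. quaternion components:
// tau_c = -0.5 * <dEdq, e_c x q>
static inline Vec3 torqueFromQGrad(const double dEdq[4], const Quat& q) {
  Quat gx = qmul(Quat(0, 1, 0, 0), q);
  Quat gy = qmul(Quat(0, 0, 1, 0), q);
  Quat gz = qmul(Quat(0, 0, 0, 1), q);
  return Vec3(
    -0.5 * (dEdq[0] * gx.w + dEdq[1] * gx.x + dEdq[2] * gx.y + dEdq[3] * gx.z),
    -0.5 * (dEdq[0] * gy.w + dEdq[1] * gy.x + dEdq[2] * gy.y + dEdq[3] * gy.z),
    -0.5 * (dEdq[0] * gz.w + dEdq[1] * gz.x + dEdq[2] * gz.y + dEdq[3] * gz.z));
}

static void addBendTwist(const Rod& rod, const Params& par,
                         std::vector<Vec3>& T, double* energy) {
  double l0 = rod.l0, I = par.Imom(), J = par.Jmom();
  int njoint = rod.active - 2;
  for (int k = 0; k < njoint; ++k) {
    const Quat& a = rod.q[k];
    const Quat& b = rod.q[k + 1];
    double Epair = 0.5 * (par.edgeE(k) + par.edgeE(k + 1));
    double Gpair = par.twist_stiffening * Epair / (2.0 * (1.0 + par.nu));
    double B[3] = { Epair * I, Epair * I, Gpair * J };
    double P[3], dPa[3][4], dPb[3][4];
    relRotIm(a, b, P, dPa, dPb);
    double dOm[3];
    for (int c = 0; c < 3; ++c) {
      double Om = (2.0 / l0) * P[c];
      double Om0 = (c == 0) ? rod.rest_darboux[k].x
                 : (c == 1) ? rod.rest_darboux[k].y : rod.rest_darboux[k].z;
      dOm[c] = Om - Om0;
      if (energy) *energy += 0.5 * l0 * B[c] * dOm[c] * dOm[c];
    }
    double dEda[4] = {0, 0, 0, 0}, dEdb[4] = {0, 0, 0, 0};
    for (int c = 0; c < 3; ++c) {
      double g = 2.0 * B[c] * dOm[c]; // dE/dP_c
      for (int i = 0; i < 4; ++i) {
        dEda[i] += g * dPa[c][i];
        dEdb[i] += g * dPb[c][i];
      }
    }
    if (!T.empty()) {
      T[k] = T[k] + torqueFromQGrad(dEda, a);
      T[k + 1] = T[k + 1] + torqueFromQGrad(dEdb, b);
    }
  }
}

static void addParallel(const Rod& rod, const Params& par,
                        std::vector<Vec3>& F, std::vector<Vec3>& T,
                        double* energy) {
  double c = par.Kp * rod.l0;
  for (int j = 0; j < rod.active - 1; ++j) {
    // edge tangent points towards the distal tip (point 0), matching the
    // frames' third director for a straight rod at rest
    Vec3 e = rod.r[j] - rod.r[j + 1];
    double len = norm(e);
    if (len <= 1e-12) stop("degenerate zero-length segment at edge %d", j + 1);
    Vec3 t = (1.0 / len) * e;
    const Quat& q = rod.q[j];
    Vec3 d3 = qdir3(q);
    Vec3 mis = d3 - t;
    if (energy) *energy += 0.5 * c * dot(mis, mis);
    if (F.empty()) continue;
    // force on points: F_j = (c/len) (I - t t^T) mis, F_{j+1} = -F_j
    Vec3 perp = mis - dot(mis, t) * t;
    Vec3 fj = (c / len) * perp;
    F[j] = F[j] + fj;
    F[j + 1] = F[j + 1] - fj;
    // torque on the frame: dE/dq = c * mis^T dd3/dq
    double dd3[3][4] = {
      { 2 * q.y,  2 * q.z,  2 * q.w, 2 * q.x },
      { -2 * q.x, -2 * q.w, 2 * q.z, 2 * q.y },
      { 0,       -4 * q.x, -4 * q.y, 0       }
    };
    double dEdq[4];
    for (int i = 0; i < 4; ++i)
      dEdq[i] = c * (mis.x * dd3[0][i] + mis.y * dd3[1][i] + mis.z * dd3[2][i]);
    T[j] = T[j] + torqueFromQGrad(dEdq, q);
  }
}

static void addStretchPenalty(const Rod& rod, const SimConfig& cfg,
                              std::vector<Vec3>& F, double* energy) {
  double ks = cfg.penalty_stiffness;
  for (int j = 0; j < rod.active - 1; ++j) {
    Vec3 e = rod.r[j + 1] - rod.r[j];
    double len = norm(e);
    if (len <= 1e-12) stop("degenerate zero-length segment at edge %d", j + 1);
    double C = len - rod.l0;
    if (energy) *energy += 0.5 * ks * C * C;
    if (F.empty()) continue;
    Vec3 d = (1.0 / len) * e;
    Vec3 f = (-ks * C) * d; // on point j+1
    F[j + 1] = F[j + 1] + f;
    F[j] = F[j] - f;
  }
}

void computeForces(const Rod& rod, const Params& par, const SimConfig& cfg,
                   std::vector<Vec3>& F, std::vector<Vec3>& T) {
  F.assign(rod.n, Vec3());
  T.assign(rod.n - 1, Vec3());
  addBendTwist(rod, par, T, nullptr);
  addParallel(rod, par, F, T, nullptr);
  if (cfg.distance_mode == 3) addStretchPenalty(rod, cfg, F, nullptr);
}

double elasticEnergy(const Rod& rod, const Params& par, const SimConfig& cfg,
                     double* bend_twist, double* parallel, double* stretch) {
  double eb = 0, ep = 0, es = 0;
  std::vector<Vec3> none;
  addBendTwist(rod, par, none, &eb);
  {
    std::vector<Vec3> noneF, noneT;
    addParallel(rod, par, noneF, noneT, &ep);
  }
  if (cfg.distance_mode == 3) {
    std::vector<Vec3> noneF;
    addStretchPenalty(rod, cfg, noneF, &es);
  }
  if (bend_twist) *bend_twist = eb;
  if (parallel) *parallel = ep;
  if (stretch) *stretch = es;
  return eb + ep + es;
}

double frameInertia(const Rod& rod, const Params& par, const SimConfig& cfg) {
  double physical = par.rho * par.area() * rod.l0 * 0.5 * par.radius * par.radius;
  double Bmax = std::max(par.Eb * par.Imom(), par.Gmod() * par.Jmom());
  double krot = 4.0 * Bmax / rod.l0 + 2.0 * par.Kp * rod.l0;
  double regularized = cfg.inertia_safety * krot * cfg.dt * cfg.dt;
  return std::max(physical, regularized);
}

// Semi-implicit Euler: velocities from forces, then (optionally) positions;
// viscous damping applied implicitly (unconditionally stable, monotone).
void integrateStep(Rod& rod, const Params& par, const SimConfig& cfg,
                   const std::vector<Vec3>& Fext, double dt, bool positions) {
  std::vector<Vec3> F, T;
  computeForces(rod, par, cfg, F, T);
  double Jrot = frameInertia(rod, par, cfg);
  double damp = 1.0 / (1.0 + cfg.damping * dt);
  // frames carry regularized inertia (see frameInertia); damp them
  // critically on their own time scale 1/(dt sqrt(safety)) so they track
  // the elastic/parallel minimum quasi-statically instead of ringing
  double wrot = 1.0 / (cfg.dt * std::sqrt(cfg.inertia_safety));
  double damp_rot = 1.0 / (1.0 + std::max(cfg.damping, 2.0 * wrot) * dt);
  for (int i = 0; i < rod.active; ++i) {
    if (rod.invm[i] <= 0) continue;
    Vec3 f = F[i] + (i < (int)Fext.size() ? Fext[i] : Vec3());
    rod.v[i] = damp * (rod.v[i] + dt * (rod.invm[i] * f + cfg.gravity));
  }
  for (int j = 0; j < rod.active - 1; ++j) {
    if (!edgeDynamic(rod, j)) continue;
    rod.w[j] = damp_rot * (rod.w[j] + (dt / Jrot) * T[j]);
    Quat dq = qmul(Quat(0, rod.w[j].x, rod.w[j].y, rod.w[j].z), rod.q[j]);
    Quat qn(rod.q[j].w + 0.5 * dt * dq.w, rod.q[j].x + 0.5 * dt * dq.x,
            rod.q[j].y + 0.5 * dt * dq.y, rod.q[j].z + 0.5 * dt * dq.z);
    rod.q[j] = qnormalize(qn);
  }
  if (positions) {
    for (int i = 0; i < rod.active; ++i)
      if (rod.invm[i] > 0) rod.r[i] = rod.r[i] + dt * rod.v[i];
  }
  for (int i = 0; i < rod.active; ++i) {
    if (!std::isfinite(rod.r[i].x + rod.r[i].y + rod.r[i].z))
      stop("numerical blow-up: non-finite position at point %d", i + 1);
    if (!std::isfinite(rod.v[i].x + rod.v[i].y + rod.v[i].z))
      stop("numerical blow-up: non-finite velocity at point %d", i + 1);
  }
}

// ---------------------------------------------------------------------------
// Insertion drive: the rod is fed through a fixed entry point along the
// insertion axis. Points with arc offset i*l0 < inserted_length are dynamic;
// the first not-yet-inserted point is the kinematic driver (infinite mass,
// velocity = push * axis); points behind it are parked on the axis.
// ---------------------------------------------------------------------------

void advanceInsertion(Rod& rod, double push, double twist, double dt) {
  double smax = (rod.n - 1) * rod.l0;
  double s = rod.s + push * dt;
  if (s < 0) s = 0;
  if (s > smax) s = smax;
  rod.s = s;
  rod.twist_angle += twist * dt;
  int k = 0; // number of inserted (dynamic) points
  while (k < rod.n && k * rod.l0 < s - 1e-15) ++k;
  rod.active = std::min(k + 1, rod.n);
  // base frame aligning d3 with the axis, twisted by the accumulated angle
  Vec3 ref = std::fabs(rod.axis.z) < 0.9 ? Vec3(0, 0, 1) : Vec3(1, 0, 0);
  Vec3 d1 = normalize(cross(ref, rod.axis));
  Vec3 d2 = cross(rod.axis, d1);
  // rotation matrix [d1 d2 axis] -> quaternion
  double m00 = d1.x, m01 = d2.x, m02 = rod.axis.x;
  double m10 = d1.y, m11 = d2.y, m12 = rod.axis.y;
  double m20 = d1.z, m21 = d2.z, m22 = rod.axis.z;
  double tr = m00 + m11 + m22;
  Quat qb;
  if (tr > 0) {
    double S = std::sqrt(tr + 1.0) * 2;
    qb = Quat(0.25 * S, (m21 - m12) / S, (m02 - m20) / S, (m10 - m01) / S);
  } else if (m00 > m11 && m00 > m22) {
    double S = std::sqrt(1.0 + m00 - m11 - m22) * 2;
    qb = Quat((m21 - m12) / S, 0.25 * S, (m01 + m10) / S, (m02 + m20) / S);
  } else if (m11 > m22) {
    double S = std::sqrt(1.0 + m11 - m00 - m22) * 2;
    qb = Quat((m02 - m20) / S, (m01 + m10) / S, 0.25 * S, (m12 + m21) / S);
  } else {
    double S = std::sqrt(1.0 + m22 - m00 - m11) * 2;
    qb = Quat((m10 - m01) / S, (m02 + m20) / S, (m12 + m21) / S, 0.25 * S);
  }
  Quat qdrive = qnormalize(qmul(qaxis(rod.axis, rod.twist_angle), qb));
  // kinematic points are placed at their step-START positions; the end-of-
  // step position update advances them by dt * v, keeping the boundary in
  // lockstep with the dynamic chain (no spurious driver-segment stretch)
  double s_pos = s - push * dt;
  for (int i = k; i < rod.n; ++i) {
    rod.r[i] = rod.entry + (s_pos - i * rod.l0) * rod.axis;
    rod.v[i] = push * rod.axis;
    rod.invm[i] = 0;
  }
  for (int i = 0; i < k; ++i)
    if (rod.invm[i] <= 0) { // newly activated point
      rod.invm[i] = 1.0 / rod.mass[i];
    }
  for (int j = std::max(k - 1, 0); j < rod.n - 1; ++j) {
    rod.q[j] = qdrive;
    rod.w[j] = twist * rod.axis;
  }
}

double compressionPercent(const Rod& rod) {
  int nseg = rod.active - 1;
  if (nseg < 1) return 0.0;
  double arc = 0;
  for (int i = 0; i < nseg; ++i) arc += norm(rod.r[i + 1] - rod.r[i]);
  double nominal = nseg * rod.l0;
  return 100.0 * (nominal - arc) / nominal;
}

// ---------------------------------------------------------------------------
// Exports
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_rod_forces(List rod, List params, List config,
                    bool bend = true, bool parallel = true, bool stretch = false) {
  Rod R = rodFromList(rod);
  Params par = paramsFromList(params);
  SimConfig cfg = configFromList(config);
  std::vector<Vec3> F(R.n, Vec3()), T(R.n - 1, Vec3());
  if (bend) addBendTwist(R, par, T, nullptr);
  if (parallel) addParallel(R, par, F, T, nullptr);
  if (stretch) addStretchPenalty(R, cfg, F, nullptr);
  NumericMatrix Fm(R.n, 3), Tm(R.n - 1, 3);
  for (int i = 0; i < R.n; ++i) { Fm(i,0)=F[i].x; Fm(i,1)=F[i].y; Fm(i,2)=F[i].z; }
  for (int j = 0; j < R.n - 1; ++j) { Tm(j,0)=T[j].x; Tm(j,1)=T[j].y; Tm(j,2)=T[j].z; }
  return List::create(_["force"] = Fm, _["torque"] = Tm);
}

// [[Rcpp::export]]
List cpp_rod_energy(List rod, List params, List config) {
  Rod R = rodFromList(rod);
  Params par = paramsFromList(params);
  SimConfig cfg = configFromList(config);
  double eb, ep, es;
  double tot = elasticEnergy(R, par, cfg, &eb, &ep, &es);
  double kin = 0;
  double Jrot = frameInertia(R, par, cfg);
  for (int i = 0; i < R.active; ++i)
    if (R.invm[i] > 0) kin += 0.5 * R.mass[i] * dot(R.v[i], R.v[i]);
  for (int j = 0; j < R.active - 1; ++j)
    if (R.invm[j] > 0 && R.invm[j + 1] > 0) kin += 0.5 * Jrot * dot(R.w[j], R.w[j]);
  return List::create(_["bend_twist"] = eb, _["parallel"] = ep,
                      _["stretch_penalty"] = es, _["kinetic"] = kin,
                      _["total"] = tot + kin);
}

// [[Rcpp::export]]
List cpp_integrate_step(List rod, List params, List config,
                        NumericMatrix external_forces, double dt) {
  Rod R = rodFromList(rod);
  Params par = paramsFromList(params);
  SimConfig cfg = configFromList(config);
  std::vector<Vec3> Fext(R.n, Vec3());
  if (external_forces.nrow() == R.n)
    for (int i = 0; i < R.n; ++i)
      Fext[i] = Vec3(external_forces(i, 0), external_forces(i, 1), external_forces(i, 2));
  integrateStep(R, par, cfg, Fext, dt, true);
  return rodToList(R);
}

// [[Rcpp::export]]
List cpp_advance_insertion(List rod, double push, double twist, double dt) {
  Rod R = rodFromList(rod);
  advanceInsertion(R, push, twist, dt);
  return rodToList(R);
}

// [[Rcpp::export]]
double cpp_compression_percent(List rod) {
  Rod R = rodFromList(rod);
  return compressionPercent(R);
}

// [[Rcpp::export]]
double cpp_frame_inertia(List rod, List params, List config) {
  Rod R = rodFromList(rod);
  return frameInertia(R, paramsFromList(params), configFromList(config));
}
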