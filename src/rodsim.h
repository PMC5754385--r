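#ifndef ENDOROD_RODSIM_H
#define ENDOROD_RODSIM_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// ---------------------------------------------------------------------------
// Small 3-vector / quaternion helpers (header-only, no dependencies).
// Quaternions are stored (w, x, y, z); frames map body -> world, and the
// third body director d3 = R(q) * e_z is kept aligned with the edge tangent
// by the parallel constraint.
// ---------------------------------------------------------------------------

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
};

inline Vec3 operator+(const Vec3& a, const Vec3& b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator-(const Vec3& a, const Vec3& b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator*(double s, const Vec3& a) { return Vec3(s * a.x, s * a.y, s * a.z); }
inline Vec3 operator*(const Vec3& a, double s) { return s * a; }
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
inline Vec3 normalize(const Vec3& a) {
  double n = norm(a);
  return (n > 0) ? (1.0 / n) * a : Vec3(0, 0, 0);
}

struct Quat {
  double w, x, y, z;
  Quat() : w(1), x(0), y(0), z(0) {}
  Quat(double w_, double x_, double y_, double z_) : w(w_), x(x_), y(y_), z(z_) {}
};

inline Quat qmul(const Quat& a, const Quat& b) {
  return Quat(a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
              a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
              a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
              a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w);
}
inline Quat qconj(const Quat& a) { return Quat(a.w, -a.x, -a.y, -a.z); }
inline double qnorm(const Quat& a) { return std::sqrt(a.w * a.w + a.x * a.x + a.y * a.y + a.z * a.z); }
inline Quat qnormalize(const Quat& a) {
  double n = qnorm(a);
  if (n <= 0) return Quat();
  return Quat(a.w / n, a.x / n, a.y / n, a.z / n);
}
// third column of R(q) for unit q
inline Vec3 qdir3(const Quat& q) {
  return Vec3(2.0 * (q.x * q.z + q.w * q.y),
              2.0 * (q.y * q.z - q.w * q.x),
              1.0 - 2.0 * (q.x * q.x + q.y * q.y));
}
inline Vec3 qrotate(const Quat& q, const Vec3& v) {
  Quat p(0, v.x, v.y, v.z);
  Quat r = qmul(qmul(q, p), qconj(q));
  return Vec3(r.x, r.y, r.z);
}
// quaternion for rotation of angle about (unit) axis
inline Quat qaxis(const Vec3& axis, double angle) {
  double h = 0.5 * angle, s = std::sin(h);
  return Quat(std::cos(h), s * axis.x, s * axis.y, s * axis.z);
}

// ---------------------------------------------------------------------------
// Rod state and parameters
// ---------------------------------------------------------------------------

struct Params {
  double Eb;        // shaft Young modulus (Pa)
  double nu;        // Poisson ratio used to derive G (dimensionless)
  double twist_stiffening; // multiplier on G = Eb/(2(1+nu))
  double radius;    // cross-section radius (m)
  double rho;       // density (kg m^-3)
  double Kp;        // parallel-constraint spring constant (N)
  double alpha;     // tip/shaft modulus ratio in (0,1]
  int    tip_points;// number of distal points with softened modulus
  double mu;        // Coulomb friction coefficient vs vessel wall

  double area() const { return M_PI * radius * radius; }
  double Imom() const { return 0.25 * M_PI * std::pow(radius, 4); }
  double Jmom() const { return 2.0 * Imom(); }
  double Gmod() const { return twist_stiffening * Eb / (2.0 * (1.0 + nu)); }
  // per-edge Young modulus with tip softening; edge j joins points j, j+1
  // (0-based, point 0 = distal tip)
  double edgeE(int j) const { return (j < tip_points) ? alpha * Eb : Eb; }
};

struct Rod {
  int n;                    // total discretized points
  int active;               // simulated points (inserted + kinematic driver)
  double l0;                // rest segment length (m)
  double s;                 // inserted length (m)
  std::vector<Vec3> r, v;   // positions, velocities (n)
  std::vector<Quat> q;      // edge frames (n-1)
  std::vector<Vec3> w;      // edge angular velocities, world frame (n-1)
  std::vector<double> mass, invm; // per point
  std::vector<Vec3> rest_darboux; // per inner joint (n-2); zero = straight
  // insertion geometry
  Vec3 entry;               // insertion point
  Vec3 axis;                // insertion axis (unit, points into the vessel)
  double twist_angle;       // accumulated proximal twist (rad)
};

struct SimConfig {
  double dt = 1e-3;
  double damping = 0.5;     // mass-proportional viscous damping (s^-1)
  Vec3 gravity;
  double stabilization = 0.2; // Baumgarte factor for contacts/concentric
  double stabilization_distance = 1.0; // distance phase: 1 = exact satisfaction
  int distance_mode = 0;    // 0 global tridiagonal, 1 local GS, 2 local Jacobi, 3 penalty
  int distance_iterations = 1;
  int outer_iterations = 1;
  int contact_iterations = 10;
  double penalty_stiffness = 0; // stretch spring constant for penalty mode (N m^-1)
  double inertia_safety = 4.0;  // frame-inertia regularization factor
};

struct ContactSet {
  std::vector<int> point;      // rod point index (0-based)
  std::vector<Vec3> normal;    // aggregated unit normal (points away from wall)
  std::vector<double> depth;   // penetration depth (m, >= 0)
  std::vector<double> mu;
  std::vector<double> jn, jt;  // accumulated impulses (filled by resolver)
};

// ---------------------------------------------------------------------------
// AABB tree
// ---------------------------------------------------------------------------

struct AabbNode {
  Vec3 lo, hi;
  int left, right;          // child node indices, -1 for leaf
  int tri_begin, tri_count; // leaf triangle range in tri_index
};

struct AabbTree {
  std::vector<AabbNode> nodes;   // node 0 = root; children have larger index
  std::vector<int> tri_index;    // permutation of 0..ntri-1
  double fat;                    // fat margin (m)
  int ntri;
  // geometry snapshot used at last build/refit
  Rcpp::NumericMatrix V;         // vertices (m)
  Rcpp::IntegerMatrix F;         // 0-based triangle indices
  long refit_touch;              // nodes touched during last refit (audit)
};

// shared routines
double pointTriangleClosest(const Vec3& p, const Vec3& a, const Vec3& b,
                            const Vec3& c, Vec3& closest);

Rod rodFromList(const Rcpp::List& rod);
Rcpp::List rodToList(const Rod& rod);
Params paramsFromList(const Rcpp::List& p);
SimConfig configFromList(const Rcpp::List& c);

void computeForces(const Rod& rod, const Params& par, const SimConfig& cfg,
                   std::vector<Vec3>& F, std::vector<Vec3>& T);
double elasticEnergy(const Rod& rod, const Params& par, const SimConfig& cfg,
                     double* bend_twist, double* parallel, double* stretch);
void integrateStep(Rod& rod, const Params& par, const SimConfig& cfg,
                   const std::vector<Vec3>& Fext, double dt, bool positions);
double frameInertia(const Rod& rod, const Params& par, const SimConfig& cfg);
void advanceInsertion(Rod& rod, double push, double twist, double dt);

void distancePhase(Rod& rod, const SimConfig& cfg, double dt,
                   std::vector<double>* residuals,
                   std::vector<Vec3>* vpseudo = nullptr);
void contactPhase(Rod& rod, ContactSet& cs, const SimConfig& cfg, double dt,
                  std::vector<Vec3>* vpseudo = nullptr);
void detectContacts(const Rod& rod, const AabbTree& tree, const Params& par,
                    ContactSet& cs);
void concentricPhase(Rod& gw, Rod& cath, const SimConfig& cfg, double dt);
double compressionPercent(const Rod& rod);

#endif
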