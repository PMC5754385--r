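#include "rodsim.h"
using namespace Rcpp;

// closest point on triangle (a,b,c) to p; returns distance (Ericson's method)
double pointTriangleClosest(const Vec3& p, const Vec3& a, const Vec3& b,
                            const Vec3& c, Vec3& closest) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { closest = a; return norm(p - a); }
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { closest = b; return norm(p - b); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    closest = a + v * ab; return norm(p - closest);
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { closest = c; return norm(p - c); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    closest = a + w * ac; return norm(p - closest);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    closest = b + w * (c - b); return norm(p - closest);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  closest = a + v * ab + w * ac;
  return norm(p - closest);
}

static inline Vec3 vrow(const NumericMatrix& V, int i) {
  return Vec3(V(i, 0), V(i, 1), V(i, 2));
}

static void triBounds(const NumericMatrix& V, const IntegerMatrix& F, int t,
                      Vec3& lo, Vec3& hi) {
  Vec3 a = vrow(V, F(t, 0)), b = vrow(V, F(t, 1)), c = vrow(V, F(t, 2));
  lo.x = std::min(a.x, std::min(b.x, c.x));
  lo.y = std::min(a.y, std::min(b.y, c.y));
  lo.z = std::min(a.z, std::min(b.z, c.z));
  hi.x = std::max(a.x, std::max(b.x, c.x));
  hi.y = std::max(a.y, std::max(b.y, c.y));
  hi.z = std::max(a.z, std::max(b.z, c.z));
}

static int buildNode(AabbTree& tree, std::vector<int>& idx, int begin, int end,
                     const std::vector<Vec3>& cent) {
  int node = tree.nodes.size();
  tree.nodes.push_back(AabbNode());
  if (end - begin <= 4) {
    AabbNode& nd = tree.nodes[node];
    nd.left = nd.right = -1;
    nd.tri_begin = begin; nd.tri_count = end - begin;
    return node;
  }
  // split at median along longest centroid axis
  Vec3 lo(1e300, 1e300, 1e300), hi(-1e300, -1e300, -1e300);
  for (int i = begin; i < end; ++i) {
    const Vec3& c = cent[idx[i]];
    lo.x = std::min(lo.x, c.x); lo.y = std::min(lo.y, c.y); lo.z = std::min(lo.z, c.z);
    hi.x = std::max(hi.x, c.x); hi.y = std::max(hi.y, c.y); hi.z = std::max(hi.z, c.z);
  }
  Vec3 ext = hi - lo;
  int axis = (ext.x >= ext.y && ext.x >= ext.z) ? 0 : (ext.y >= ext.z ? 1 : 2);
  int mid = (begin + end) / 2;
  std::nth_element(idx.begin() + begin, idx.begin() + mid, idx.begin() + end,
                   [&](int a, int b) {
                     double ca = axis == 0 ? cent[a].x : axis == 1 ? cent[a].y : cent[a].z;
                     double cb = axis == 0 ? cent[b].x : axis == 1 ? cent[b].y : cent[b].z;
                     return ca < cb;
                   });
  int left = buildNode(tree, idx, begin, mid, cent);
  int right = buildNode(tree, idx, mid, end, cent);
  AabbNode& nd = tree.nodes[node];
  nd.left = left; nd.right = right;
  nd.tri_begin = -1; nd.tri_count = 0;
  return node;
}

static void refitBoxes(AabbTree& tree) {
  tree.refit_touch = 0;
  for (int i = tree.nodes.size() - 1; i >= 0; --i) {
    AabbNode& nd = tree.nodes[i];
    ++tree.refit_touch;
    if (nd.left < 0) {
      Vec3 lo(1e300, 1e300, 1e300), hi(-1e300, -1e300, -1e300);
      for (int k = nd.tri_begin; k < nd.tri_begin + nd.tri_count; ++k) {
        Vec3 tlo, thi;
        triBounds(tree.V, tree.F, tree.tri_index[k], tlo, thi);
        lo.x = std::min(lo.x, tlo.x); lo.y = std::min(lo.y, tlo.y); lo.z = std::min(lo.z, tlo.z);
        hi.x = std::max(hi.x, thi.x); hi.y = std::max(hi.y, thi.y); hi.z = std::max(hi.z, thi.z);
      }
      nd.lo = lo - Vec3(tree.fat, tree.fat, tree.fat);
      nd.hi = hi + Vec3(tree.fat, tree.fat, tree.fat);
    } else {
      const AabbNode& L = tree.nodes[nd.left];
      const AabbNode& R = tree.nodes[nd.right];
      nd.lo.x = std::min(L.lo.x, R.lo.x); nd.lo.y = std::min(L.lo.y, R.lo.y);
      nd.lo.z = std::min(L.lo.z, R.lo.z);
      nd.hi.x = std::max(L.hi.x, R.hi.x); nd.hi.y = std::max(L.hi.y, R.hi.y);
      nd.hi.z = std::max(L.hi.z, R.hi.z);
    }
  }
}

static inline double boxDist2(const AabbNode& nd, const Vec3& p) {
  double d2 = 0, d;
  d = std::max(std::max(nd.lo.x - p.x, p.x - nd.hi.x), 0.0); d2 += d * d;
  d = std::max(std::max(nd.lo.y - p.y, p.y - nd.hi.y), 0.0); d2 += d * d;
  d = std::max(std::max(nd.lo.z - p.z, p.z - nd.hi.z), 0.0); d2 += d * d;
  return d2;
}

static void queryTree(const AabbTree& tree, const Vec3& center, double radius,
                      std::vector<int>& out) {
  if (tree.nodes.empty()) return;
  double r2 = radius * radius;
  std::vector<int> stack;
  stack.push_back(0);
  while (!stack.empty()) {
    int ni = stack.back(); stack.pop_back();
    const AabbNode& nd = tree.nodes[ni];
    if (boxDist2(nd, center) > r2) continue;
    if (nd.left < 0) {
      for (int k = nd.tri_begin; k < nd.tri_begin + nd.tri_count; ++k)
        out.push_back(tree.tri_index[k]);
    } else {
      stack.push_back(nd.left);
      stack.push_back(nd.right);
    }
  }
}

// aggregated contact for one sphere (centre p, radius r) against the mesh;
// returns true if in contact
static bool sphereContact(const AabbTree& tree, const Vec3& p, double r,
                          Vec3& normal, double& depth) {
  std::vector<int> cand;
  queryTree(tree, p, r, cand);
  Vec3 acc; double dmax = -1; Vec3 ndeep;
  for (int t : cand) {
    Vec3 a = vrow(tree.V, tree.F(t, 0));
    Vec3 b = vrow(tree.V, tree.F(t, 1));
    Vec3 c = vrow(tree.V, tree.F(t, 2));
    Vec3 cp;
    double d = pointTriangleClosest(p, a, b, c, cp);
    if (d >= r) continue; // contact band is symmetric about the surface
    Vec3 nt = normalize(cross(b - a, c - a)); // oriented into the lumen
    double side = dot(p - cp, nt) >= 0 ? 1.0 : -1.0;
    double pen = r - side * d;
    if (pen <= 0) continue;
    acc = acc + pen * nt;
    if (pen > dmax) { dmax = pen; ndeep = nt; }
  }
  if (dmax < 0) return false;
  double an = norm(acc);
  normal = (an > 1e-12) ? (1.0 / an) * acc : ndeep; // opposing-wall fallback
  depth = dmax;
  return true;
}

void detectContacts(const Rod& rod, const AabbTree& tree, const Params& par,
                    ContactSet& cs) {
  cs.point.clear(); cs.normal.clear(); cs.depth.clear(); cs.mu.clear();
  for (int i = 0; i < rod.active; ++i) {
    if (rod.invm[i] <= 0) continue;
    Vec3 n; double depth;
    if (sphereContact(tree, rod.r[i], par.radius, n, depth)) {
      cs.point.push_back(i);
      cs.normal.push_back(n);
      cs.depth.push_back(depth);
      cs.mu.push_back(par.mu);
    }
  }
}

// ---------------------------------------------------------------------------
// Exports
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_build_tree(NumericMatrix V, IntegerMatrix Fidx, double fat_margin) {
  if (Fidx.nrow() < 1) stop("empty mesh");
  XPtr<AabbTree> ptr(new AabbTree(), true);
  AabbTree& tree = *ptr;
  tree.fat = fat_margin;
  tree.ntri = Fidx.nrow();
  tree.V = clone(V);
  IntegerMatrix F0(Fidx.nrow(), 3);
  for (int t = 0; t < Fidx.nrow(); ++t)
    for (int k = 0; k < 3; ++k) F0(t, k) = Fidx(t, k) - 1;
  tree.F = F0;
  std::vector<Vec3> cent(tree.ntri);
  for (int t = 0; t < tree.ntri; ++t) {
    Vec3 a = vrow(tree.V, F0(t, 0)), b = vrow(tree.V, F0(t, 1)), c = vrow(tree.V, F0(t, 2));
    cent[t] = (1.0 / 3.0) * (a + b + c);
  }
  tree.tri_index.resize(tree.ntri);
  for (int t = 0; t < tree.ntri; ++t) tree.tri_index[t] = t;
  buildNode(tree, tree.tri_index, 0, tree.ntri, cent);
  refitBoxes(tree);
  return ptr;
}

// [[Rcpp::export]]
long cpp_refit_tree(SEXP treeptr, NumericMatrix V) {
  XPtr<AabbTree> ptr(treeptr);
  if (V.nrow() != ptr->V.nrow())
    stop("refit requires identical mesh topology (vertex count changed)");
  ptr->V = clone(V);
  refitBoxes(*ptr);
  return ptr->refit_touch;
}

// [[Rcpp::export]]
IntegerVector cpp_query_tree(SEXP treeptr, NumericVector center, double radius) {
  XPtr<AabbTree> ptr(treeptr);
  std::vector<int> out;
  queryTree(*ptr, Vec3(center[0], center[1], center[2]), radius, out);
  IntegerVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = out[i] + 1;
  return res;
}

// [[Rcpp::export]]
List cpp_tree_info(SEXP treeptr) {
  XPtr<AabbTree> ptr(treeptr);
  int nn = ptr->nodes.size();
  NumericMatrix lo(nn, 3), hi(nn, 3);
  IntegerVector left(nn), right(nn), tb(nn), tc(nn);
  for (int i = 0; i < nn; ++i) {
    const AabbNode& nd = ptr->nodes[i];
    lo(i, 0) = nd.lo.x; lo(i, 1) = nd.lo.y; lo(i, 2) = nd.lo.z;
    hi(i, 0) = nd.hi.x; hi(i, 1) = nd.hi.y; hi(i, 2) = nd.hi.z;
    left[i] = nd.left + 1; right[i] = nd.right + 1; // 1-based, 0 = leaf
    tb[i] = nd.tri_begin; tc[i] = nd.tri_count;
  }
  IntegerVector tidx(ptr->tri_index.size());
  for (size_t i = 0; i < ptr->tri_index.size(); ++i) tidx[i] = ptr->tri_index[i] + 1;
  return List::create(_["lo"] = lo, _["hi"] = hi, _["left"] = left,
                      _["right"] = right, _["tri_begin"] = tb,
                      _["tri_count"] = tc, _["tri_index"] = tidx,
                      _["fat_margin"] = ptr->fat,
                      _["refit_touch"] = (double)ptr->refit_touch);
}

// [[Rcpp::export]]
List cpp_narrow_contacts(NumericMatrix points, double radius, double mu,
                         SEXP treeptr) {
  XPtr<AabbTree> ptr(treeptr);
  std::vector<int> pts; std::vector<Vec3> nrm; std::vector<double> dep;
  for (int i = 0; i < points.nrow(); ++i) {
    Vec3 p(points(i, 0), points(i, 1), points(i, 2));
    Vec3 n; double depth;
    if (sphereContact(*ptr, p, radius, n, depth)) {
      pts.push_back(i + 1); nrm.push_back(n); dep.push_back(depth);
    }
  }
  int nc = pts.size();
  IntegerVector pi(nc); NumericMatrix nm(nc, 3); NumericVector dv(nc), mv(nc);
  for (int c = 0; c < nc; ++c) {
    pi[c] = pts[c];
    nm(c, 0) = nrm[c].x; nm(c, 1) = nrm[c].y; nm(c, 2) = nrm[c].z;
    dv[c] = dep[c]; mv[c] = mu;
  }
  return List::create(_["point_index"] = pi, _["normal"] = nm,
                      _["penetration_depth"] = dv, _["friction_coefficient"] = mv);
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix points, NumericMatrix V,
                                      IntegerMatrix Fidx) {
  NumericVector out(points.nrow());
  for (int i = 0; i < points.nrow(); ++i) {
    Vec3 p(points(i, 0), points(i, 1), points(i, 2));
    double best = std::numeric_limits<double>::max();
    for (int t = 0; t < Fidx.nrow(); ++t) {
      Vec3 a = vrow(V, Fidx(t, 0) - 1), b = vrow(V, Fidx(t, 1) - 1),
           c = vrow(V, Fidx(t, 2) - 1);
      Vec3 cp;
      double d = pointTriangleClosest(p, a, b, c, cp);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_min_dist_polyline(NumericMatrix points, NumericMatrix line) {
  int np = points.nrow(), nl = line.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    Vec3 p(points(i, 0), points(i, 1), points(i, 2));
    double best = std::numeric_limits<double>::max();
    for (int j = 0; j + 1 < nl; ++j) {
      Vec3 a(line(j, 0), line(j, 1), line(j, 2));
      Vec3 b(line(j + 1, 0), line(j + 1, 1), line(j + 1, 2));
      Vec3 ab = b - a;
      double L2 = dot(ab, ab);
      double w = (L2 > 0) ? std::min(1.0, std::max(0.0, dot(p - a, ab) / L2)) : 0.0;
      Vec3 cp = a + w * ab;
      double d = norm(p - cp);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}
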