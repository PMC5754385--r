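#include "rodsim.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Full physics step driver. Each step:
//   1. advance the insertion drive (kinematic proximal boundary),
//   2. integrate elastic/parallel(/penalty) forces into velocities and
//      frame quaternions (semi-implicit Euler, implicit viscous damping),
//   3. detect rod/vessel contacts (broad AABB + sphere-vs-triangle narrow),
//   4. block-iterative PGS: distance phase -> (concentric) -> contact phase,
//      re-linearized at predicted positions each outer iteration,
//   5. position update from corrected velocities.
// ---------------------------------------------------------------------------

static void pgsOuter(Rod& rod, ContactSet& cs, const SimConfig& cfg, double dt,
                     bool have_contacts, std::vector<Vec3>& vpseudo) {
  for (int it = 0; it < cfg.outer_iterations; ++it) {
    distancePhase(rod, cfg, dt, nullptr, &vpseudo);
    if (have_contacts) contactPhase(rod, cs, cfg, dt, &vpseudo);
  }
}

static double maxSegmentError(const Rod& rod) {
  double m = 0;
  for (int i = 0; i < rod.active - 1; ++i)
    m = std::max(m, std::fabs(norm(rod.r[i + 1] - rod.r[i]) - rod.l0));
  return m;
}

static double maxSpeed(const Rod& rod) {
  double m = 0;
  for (int i = 0; i < rod.active; ++i)
    if (rod.invm[i] > 0) m = std::max(m, norm(rod.v[i]));
  return m;
}

// [[Rcpp::export]]
List cpp_sim_run(List rod, List params, List config, SEXP treeptr,
                 NumericMatrix schedule, double duration, int record_stride,
                 double settle_tol, int settle_max_steps) {
  Rod R = rodFromList(rod);
  Params par = paramsFromList(params);
  SimConfig cfg = configFromList(config);
  double dt = cfg.dt;
  bool have_mesh = treeptr != R_NilValue;
  AabbTree* tree = nullptr;
  if (have_mesh) tree = XPtr<AabbTree>(treeptr).get();
  int nsched = schedule.nrow();
  bool driven = nsched > 0;
  long nsteps = (long)std::ceil(duration / dt - 1e-9);
  std::vector<double> rec_t, rec_comp, rec_viol;
  std::vector<int> rec_active, rec_ncontact;
  List rec_traj;
  ContactSet cs;
  std::vector<Vec3> noFext;
  long step = 0;
  bool settling = false;
  long settle_steps = 0;
  int srow = 0;
  while (true) {
    if (step >= nsteps) {
      if (settle_tol <= 0) break;
      settling = true;
      if (settle_steps >= settle_max_steps) break;
      if (maxSpeed(R) < settle_tol) break;
      ++settle_steps;
    }
    double t = step * dt;
    double push = 0, twist = 0;
    if (driven && !settling) {
      while (srow + 1 < nsched && schedule(srow + 1, 0) <= t + 1e-12) ++srow;
      push = schedule(srow, 1);
      twist = schedule(srow, 2);
    }
    if (driven) advanceInsertion(R, push, twist, dt);
    integrateStep(R, par, cfg, noFext, dt, false);
    bool have_contacts = false;
    if (have_mesh) {
      detectContacts(R, *tree, par, cs);
      have_contacts = !cs.point.empty();
    }
    std::vector<Vec3> vpseudo(R.n, Vec3());
    pgsOuter(R, cs, cfg, dt, have_contacts, vpseudo);
    for (int i = 0; i < R.active; ++i) // kinematic points carry drive velocity
      R.r[i] = R.r[i] + dt * (R.v[i] + vpseudo[i]);
    ++step;
    if (record_stride > 0 && (step % record_stride == 0 || step == nsteps)) {
      rec_t.push_back(step * dt);
      rec_comp.push_back(compressionPercent(R));
      rec_viol.push_back(maxSegmentError(R));
      rec_active.push_back(R.active);
      rec_ncontact.push_back(cs.point.size());
      NumericMatrix P(R.active, 3);
      for (int i = 0; i < R.active; ++i) {
        P(i, 0) = R.r[i].x; P(i, 1) = R.r[i].y; P(i, 2) = R.r[i].z;
      }
      rec_traj.push_back(P);
    }
    if (step > nsteps + settle_max_steps + 10) break; // safety
  }
  return List::create(
    _["rod"] = rodToList(R),
    _["steps"] = (double)step,
    _["settle_steps"] = (double)settle_steps,
    _["final_compression_percent"] = compressionPercent(R),
    _["final_max_segment_error"] = maxSegmentError(R),
    _["final_max_speed"] = maxSpeed(R),
    _["final_contact_count"] = (int)cs.point.size(),
    _["trace"] = List::create(
      _["time"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["compression_percent"] = NumericVector(rec_comp.begin(), rec_comp.end()),
      _["max_segment_error"] = NumericVector(rec_viol.begin(), rec_viol.end()),
      _["active_count"] = IntegerVector(rec_active.begin(), rec_active.end()),
      _["contact_count"] = IntegerVector(rec_ncontact.begin(), rec_ncontact.end()),
      _["points"] = rec_traj));
}

// one PGS step over already-integrated tentative velocities, with contacts
// supplied per instrument (list of lists with point_index/normal/depth/mu)
// [[Rcpp::export]]
List cpp_pgs_step(List instruments, List contacts, List config, double dt) {
  SimConfig cfg = configFromList(config);
  int ninst = instruments.size();
  std::vector<Rod> rods(ninst);
  std::vector<ContactSet> css(ninst);
  for (int k = 0; k < ninst; ++k) {
    rods[k] = rodFromList(instruments[k]);
    if (contacts.size() > k && !Rf_isNull(contacts[k])) {
      List ck = contacts[k];
      IntegerVector pi = ck["point_index"];
      NumericMatrix nm = ck["normal"];
      NumericVector dv = ck["penetration_depth"], mv = ck["friction_coefficient"];
      for (int c = 0; c < pi.size(); ++c) {
        css[k].point.push_back(pi[c] - 1);
        css[k].normal.push_back(Vec3(nm(c, 0), nm(c, 1), nm(c, 2)));
        css[k].depth.push_back(dv[c]);
        css[k].mu.push_back(mv[c]);
      }
    }
  }
  std::vector<std::vector<Vec3> > vps(ninst);
  for (int k = 0; k < ninst; ++k) vps[k].assign(rods[k].n, Vec3());
  for (int it = 0; it < cfg.outer_iterations; ++it) {
    for (int k = 0; k < ninst; ++k)
      distancePhase(rods[k], cfg, dt, nullptr, &vps[k]);
    if (ninst >= 2) concentricPhase(rods[0], rods[1], cfg, dt);
    for (int k = 0; k < ninst; ++k)
      if (!css[k].point.empty()) contactPhase(rods[k], css[k], cfg, dt, &vps[k]);
  }
  List out(ninst), jn(ninst), jt(ninst);
  for (int k = 0; k < ninst; ++k) {
    for (int i = 0; i < rods[k].active; ++i)
      if (rods[k].invm[i] > 0)
        rods[k].r[i] = rods[k].r[i] + dt * (rods[k].v[i] + vps[k][i]);
    out[k] = rodToList(rods[k]);
    jn[k] = NumericVector(css[k].jn.begin(), css[k].jn.end());
    jt[k] = NumericVector(css[k].jt.begin(), css[k].jt.end());
  }
  return List::create(_["instruments"] = out, _["normal_impulses"] = jn,
                      _["tangential_impulses"] = jt);
}
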