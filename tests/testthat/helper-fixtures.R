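# Shared fixtures and independent oracles (plain R, no reuse of the
# compiled code paths they check).

# a small rod with deterministic position/frame perturbation
perturbed_rod <- function(n = 8, seed = 1, pos_scale = 2e-4,
                          frame_scale = 0.05, params = material_params()) {
  set.seed(seed)
  rod <- build_rod(n, (n - 1) * 1e-3, params)
  rod$points <- rod$points + matrix(rnorm(3 * n, 0, pos_scale), n, 3)
  q <- rod$frames + matrix(rnorm(4 * (n - 1), 0, frame_scale), n - 1, 4)
  rod$frames <- q / sqrt(rowSums(q^2))
  rod$velocities <- matrix(rnorm(3 * n, 0, 1e-3), n, 3)
  rod
}

# rotate frame j of a rod by `ang` about world axis (for finite differences)
rotate_frame <- function(rod, j, axis, ang) {
  q <- rod$frames[j, ]
  d <- c(cos(ang / 2), sin(ang / 2) * axis)
  rod$frames[j, ] <- c(
    d[1] * q[1] - d[2] * q[2] - d[3] * q[3] - d[4] * q[4],
    d[1] * q[2] + d[2] * q[1] + d[3] * q[4] - d[4] * q[3],
    d[1] * q[3] - d[2] * q[4] + d[3] * q[1] + d[4] * q[2],
    d[1] * q[4] + d[2] * q[3] - d[3] * q[2] + d[4] * q[1])
  rod
}

# dense-matrix oracle for the distance-constraint Schur system
dense_distance_solve <- function(rod, sys) {
  n <- rod$active_count
  ns <- n - 1
  d <- sys$directions
  J <- matrix(0, ns, 3 * n)
  for (i in seq_len(ns)) {
    J[i, (3 * (i - 1) + 1):(3 * i)] <- -d[i, ]
    J[i, (3 * i + 1):(3 * i + 3)] <- d[i, ]
  }
  Minv <- diag(rep(rod$inv_mass[seq_len(n)], each = 3))
  A <- J %*% Minv %*% t(J)
  lam <- solve(A, sys$rhs)
  list(A = A, lambda = lam,
       dv = matrix(Minv %*% t(J) %*% lam, n, 3, byrow = TRUE))
}

# independent closest point on a triangle (barycentric projection + edges)
oracle_triangle_closest <- function(p, a, b, c) {
  n <- pracma_cross_h(b - a, c - a)
  n2 <- sum(n^2)
  seg_closest <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w^2)
    t <- min(1, max(0, t))
    u + t * w
  }
  if (n2 > 0) {
    # barycentric coordinates of the in-plane projection
    v0 <- b - a; v1 <- c - a; v2 <- p - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1)
      return(a + v * v0 + w * v1)
  }
  cand <- rbind(seg_closest(p, a, b), seg_closest(p, b, c),
                seg_closest(p, c, a))
  cand[which.min(rowSums(sweep(cand, 2, p)^2)), ]
}

oracle_point_triangle <- function(p, a, b, c) {
  sqrt(sum((p - oracle_triangle_closest(p, a, b, c))^2))
}

pracma_cross_h <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# brute-force contact oracle matching the narrow-phase aggregation rule
oracle_contacts <- function(points, mesh, radius) {
  out <- list(point_index = integer(0), normal = NULL, depth = numeric(0))
  normals <- NULL
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    acc <- c(0, 0, 0); dmax <- -1; ndeep <- c(0, 0, 0)
    for (t in seq_len(nrow(mesh$faces))) {
      a <- mesh$vertices[mesh$faces[t, 1], ]
      b <- mesh$vertices[mesh$faces[t, 2], ]
      cc <- mesh$vertices[mesh$faces[t, 3], ]
      cp <- oracle_triangle_closest(p, a, b, cc)
      d <- sqrt(sum((p - cp)^2))
      if (d >= radius) next # contact band is symmetric about the surface
      nt <- mesh$normals[t, ]
      side <- if (sum((p - cp) * nt) >= 0) 1 else -1
      pen <- radius - side * d
      if (pen <= 0) next
      acc <- acc + pen * nt
      if (pen > dmax) { dmax <- pen; ndeep <- nt }
    }
    if (dmax < 0) next
    nn <- if (sqrt(sum(acc^2)) > 1e-12) acc / sqrt(sum(acc^2)) else ndeep
    out$point_index <- c(out$point_index, i)
    normals <- rbind(normals, nn)
    out$depth <- c(out$depth, dmax)
  }
  out$normal <- normals
  out
}

# small open tube for collision tests
small_tube <- function(segments = 16L, axial_step = 3e-3, capped = FALSE) {
  make_tube_phantom(2.5e-3, 90, 0.02, c(0.03, 0.03), segments = segments,
                    axial_step = axial_step, capped = capped)
}

# small calibration setup shared by calibration tests: a lubricated
# (hydrophilic, frictionless) wire settled under strong damping, the
# regime where the equilibrium shape depends smoothly on the material
# parameters
small_calibration_problem <- function(params = material_params(friction_coefficient = 0)) {
  ph <- make_tube_phantom(2e-3, 60, 0.025, c(0.03, 0.03), capped = TRUE)
  calibration_problem(
    ph, reference_centreline(cbind(c(0, 1), 0, 0)),
    insertion_drive(0, 0.04, 0), duration = 1.375, params = params,
    free = c("young_modulus_shaft", "tip_modulus_ratio"),
    lower = list(young_modulus_shaft = 1e6, tip_modulus_ratio = 0.05),
    upper = list(young_modulus_shaft = 2.5e7, tip_modulus_ratio = 1),
    n_points = 61, total_length = 0.06,
    config = sim_config(damping = 5),
    settle_tol = 1e-5, settle_max_steps = 6000L)
}

make_inserted_rod <- function(scenario) {
  rod <- build_rod(scenario$n_points, scenario$total_length, scenario$params,
                   base_position = scenario$phantom$centreline$points[1, ],
                   base_axis = c(1, 0, 0), inserted_length = 0)
  advance_insertion(rod, dt = 0)
}

# points on a phantom centreline at given arc positions
tube_path_points <- function(phantom, s) {
  cl <- phantom$centreline
  cbind(stats::approx(cl$arc, cl$points[, 1], xout = s, rule = 2)$y,
        stats::approx(cl$arc, cl$points[, 2], xout = s, rule = 2)$y,
        stats::approx(cl$arc, cl$points[, 3], xout = s, rule = 2)$y)
}
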