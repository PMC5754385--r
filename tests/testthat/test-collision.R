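test_that("tree construction satisfies containment and partitions triangles", {
  # minimal mesh: one triangle
  m1 <- triangle_mesh(rbind(c(0, 0, 0), c(1e-3, 0, 0), c(0, 1e-3, 0)),
                      rbind(c(1, 2, 3)))
  t1 <- build_aabb_tree(m1, fat_margin = 1e-4)
  s1 <- tree_structure(t1)
  expect_equal(length(s1$left), 1)
  expect_equal(s1$tri_count[1], 1)
  expect_equal(s1$lo[1, ], c(-1e-4, -1e-4, -1e-4), tolerance = 1e-12)
  expect_equal(s1$hi[1, ], c(1e-3, 1e-3, 0) + 1e-4, tolerance = 1e-12)

  tube <- small_tube()
  tree <- build_aabb_tree(tube$mesh, fat_margin = 8e-4)
  s <- tree_structure(tree)
  # recursive containment: every child box inside its parent box
  for (i in seq_along(s$left)) {
    for (ch in c(s$left[i], s$right[i])) {
      if (ch == 0) next
      expect_true(all(s$lo[ch, ] >= s$lo[i, ] - 1e-12))
      expect_true(all(s$hi[ch, ] <= s$hi[i, ] + 1e-12))
    }
  }
  # leaves partition the triangle set
  leaves <- which(s$left == 0)
  got <- unlist(lapply(leaves, function(i)
    s$tri_index[(s$tri_begin[i] + 1):(s$tri_begin[i] + s$tri_count[i])]))
  expect_setequal(got, seq_len(nrow(tube$mesh$faces)))
  expect_equal(length(got), nrow(tube$mesh$faces))
})

test_that("refit is exact for rigid motion, bounds deformations, touches each node once", {
  tube <- small_tube()
  tree <- build_aabb_tree(tube$mesh, fat_margin = 8e-4)
  s0 <- tree_structure(tree)

  refit_aabb_tree(tree, tube$mesh) # unmoved: identical boxes
  s1 <- tree_structure(tree)
  expect_equal(s1$lo, s0$lo, tolerance = 1e-15)
  expect_equal(s1$hi, s0$hi, tolerance = 1e-15)
  expect_equal(s1$refit_touch, length(s1$left))

  tr <- c(5e-3, -2e-3, 1e-3)
  moved <- tube$mesh
  moved$vertices <- sweep(moved$vertices, 2, tr, `+`)
  refit_aabb_tree(tree, moved)
  s2 <- tree_structure(tree)
  expect_equal(s2$lo, sweep(s0$lo, 2, tr, `+`), tolerance = 1e-12)
  expect_equal(s2$hi, sweep(s0$hi, 2, tr, `+`), tolerance = 1e-12)
  expect_equal(s2$refit_touch, length(s2$left)) # independent of motion size

  # non-rigid deformation: per-triangle brute-force boxes stay inside
  # their fattened leaf boxes
  set.seed(6)
  warped <- tube$mesh
  warped$vertices <- warped$vertices +
    2e-4 * outer(sin(warped$vertices[, 1] * 300), c(0, 1, 1))
  refit_aabb_tree(tree, warped)
  s3 <- tree_structure(tree)
  leaves <- which(s3$left == 0)
  for (i in leaves) {
    tris <- s3$tri_index[(s3$tri_begin[i] + 1):(s3$tri_begin[i] + s3$tri_count[i])]
    vv <- warped$vertices[as.vector(t(warped$faces[tris, , drop = FALSE])), ,
                          drop = FALSE]
    expect_true(all(sweep(vv, 2, s3$lo[i, ], `-`) >= -1e-12))
    expect_true(all(sweep(vv, 2, s3$hi[i, ], `-`) <= 1e-12))
  }

  other <- make_tube_phantom(2e-3, 45, 0.02, c(0.02, 0.02), segments = 8L)
  expect_error(refit_aabb_tree(tree, other$mesh), "topology")
})

test_that("broad-phase queries are conservative supersets of true hits", {
  tube <- small_tube()
  tree <- build_aabb_tree(tube$mesh, fat_margin = 8e-4)
  V <- tube$mesh$vertices; F_ <- tube$mesh$faces

  far <- query_candidates(tree, c(1, 1, 1), 1e-3)
  expect_length(far, 0)

  all_tri <- query_candidates(tree, colMeans(V), 1)
  expect_setequal(all_tri, seq_len(nrow(F_)))

  set.seed(8)
  for (case in 1:100) {
    ctr <- V[sample(nrow(V), 1), ] + rnorm(3, 0, 2e-3)
    rad <- runif(1, 5e-4, 4e-3)
    cand <- query_candidates(tree, ctr, rad)
    truth <- which(vapply(seq_len(nrow(F_)), function(t)
      oracle_point_triangle(ctr, V[F_[t, 1], ], V[F_[t, 2], ],
                            V[F_[t, 3], ]) <= rad, logical(1)))
    expect_true(all(truth %in% cand))
  }
})

test_that("narrow phase matches closed forms and the brute-force oracle", {
  p <- material_params()
  # separation: no contact
  m1 <- triangle_mesh(rbind(c(0, 0, 0), c(1e-2, 0, 0), c(0, 1e-2, 0)),
                      rbind(c(1, 2, 3)))
  tr1 <- build_aabb_tree(m1, 8e-4)
  none <- narrow_phase_contacts(matrix(c(2e-3, 2e-3, 5e-3), 1, 3), tr1, p)
  expect_length(none$point_index, 0)

  # single penetrating triangle: the contact normal is that triangle's
  one <- narrow_phase_contacts(matrix(c(2e-3, 2e-3, 2e-4), 1, 3), tr1, p)
  expect_equal(one$point_index, 1L)
  expect_equal(one$normal[1, ], m1$normals[1, ], tolerance = 1e-12)
  expect_equal(one$penetration_depth[1], p$radius - 2e-4, tolerance = 1e-12)

  # symmetric wedge: aggregated normal is the normalized bisector
  wedge <- triangle_mesh(
    rbind(c(-1e-2, 0, 0), c(1e-2, 0, 0), c(0, 1e-2, 1e-2),
          c(0, 1e-2, -1e-2)),
    rbind(c(1, 2, 3), c(2, 1, 4)))
  trw <- build_aabb_tree(wedge, 8e-4)
  ctc <- narrow_phase_contacts(matrix(c(0, 1e-4, 0), 1, 3), trw, p)
  bis <- (wedge$normals[1, ] + wedge$normals[2, ])
  bis <- bis / sqrt(sum(bis^2))
  expect_equal(ctc$normal[1, ], bis, tolerance = 1e-9)

  # BVH pipeline == brute force over all triangles, 50 random poses
  tube <- small_tube()
  tree <- build_aabb_tree(tube$mesh, 8e-4)
  set.seed(10)
  for (case in 1:50) {
    s <- runif(5, 0, tube$total_arc)
    base <- tube_path_points(tube, s)
    pts <- base + matrix(rnorm(15, 0, 1.2e-3), 5, 3)
    got <- narrow_phase_contacts(pts, tree, p)
    want <- oracle_contacts(pts, tube$mesh, p$radius)
    expect_equal(got$point_index, want$point_index)
    if (length(want$point_index)) {
      expect_equal(got$penetration_depth, want$depth, tolerance = 1e-10)
      expect_equal(unname(got$normal), unname(want$normal), tolerance = 1e-9)
    }
  }
})

test_that("contact resolution respects unilaterality and the Coulomb cone", {
  p <- material_params()
  rod <- build_rod(5, 0.004, p)

  # separating contact: no impulse
  sep <- rod
  sep$velocities[3, ] <- c(0, 0.05, 0)
  contacts <- list(point_index = 3L, normal = matrix(c(0, 1, 0), 1, 3),
                   penetration_depth = 0, friction_coefficient = 0.3)
  r1 <- resolve_contacts(sep, contacts)
  expect_equal(r1$normal_impulse, 0)
  expect_equal(r1$rod$velocities, sep$velocities, tolerance = 1e-15)

  # head-on frictionless impact: normal velocity becomes non-negative,
  # tangential untouched
  head <- rod
  head$velocities[3, ] <- c(0.02, -0.08, 0)
  c0 <- contacts; c0$friction_coefficient <- 0
  r2 <- resolve_contacts(head, c0)
  expect_gte(r2$rod$velocities[3, 2], -1e-12)
  expect_equal(r2$rod$velocities[3, 1], 0.02, tolerance = 1e-12)

  # oblique impact with friction: |j_t| <= mu j_n within 1e-12
  obl <- rod
  obl$velocities[3, ] <- c(0.05, -0.03, 0.01)
  c3 <- contacts; c3$penetration_depth <- 5e-5
  r3 <- resolve_contacts(obl, c3)
  expect_lte(r3$tangential_impulse, 0.3 * r3$normal_impulse + 1e-12)
})

test_that("resolved contacts settle without sinking into the wall", {
  # a rod resting under gravity on the tube floor: steady penetration
  # stays below 10% of the instrument radius
  p <- material_params()
  tube <- make_tube_phantom(2.5e-3, 0, 0.03, c(0.02, 0.02), capped = FALSE)
  rod <- build_rod(16, 0.015, p,
                   base_position = c(0.03, 0, 0), base_axis = c(-1, 0, 0))
  cfg <- sim_config(damping = 5, gravity = c(0, 0, -9.81))
  sim <- simulate_insertion(rod, p, tube, drive = NULL, config = cfg,
                            duration = 2)
  pts <- sim$rod$points
  depth <- (sqrt(pts[, 2]^2 + pts[, 3]^2) + p$radius) - tube$inner_radius
  expect_gt(sim$final_contact_count, 0)
  expect_lt(max(depth), 0.1 * p$radius)
})
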