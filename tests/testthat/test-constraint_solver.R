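test_that("the assembled distance system is the exact constraint Schur complement", {
  p <- material_params()
  # two-segment closed form with equal masses
  rod3 <- perturbed_rod(3, seed = 2)
  sys <- assemble_distance_system(rod3, dt = 1e-3, stabilization = 1)
  m <- rod3$mass[1]
  expect_equal(sys$diagonal, rep(2 / m, 2), tolerance = 1e-12)
  expect_equal(sys$off_diagonal,
               -(1 / m) * sum(sys$directions[1, ] * sys$directions[2, ]),
               tolerance = 1e-12)

  # a fixed (infinite-mass) proximal point drops out of the diagonal
  fixed <- rod3
  fixed$inv_mass[3] <- 0
  sysf <- assemble_distance_system(fixed, dt = 1e-3, stabilization = 1)
  expect_equal(sysf$diagonal[2], 1 / m, tolerance = 1e-12)

  # dense Jacobian oracle on an 8-point rod
  rod8 <- perturbed_rod(8, seed = 4)
  sys8 <- assemble_distance_system(rod8, dt = 1e-3, stabilization = 1,
                                   predicted = TRUE)
  dense <- dense_distance_solve(rod8, sys8)
  expect_equal(sys8$diagonal, diag(dense$A), tolerance = 1e-12 * max(diag(dense$A)))
  expect_equal(sys8$off_diagonal, dense$A[cbind(1:6, 2:7)],
               tolerance = 1e-12 * max(diag(dense$A)))
})

test_that("global tridiagonal solve equals the dense solve on random rods", {
  p <- material_params()
  for (case in 1:50) {
    n <- sample(4:64, 1)
    rod <- perturbed_rod(n, seed = 100 + case)
    sys <- assemble_distance_system(rod, dt = 1e-3, stabilization = 1,
                                    predicted = TRUE)
    dense <- dense_distance_solve(rod, sys)
    res <- solve_distance_global(rod, dt = 1e-3, stabilization = 1)
    vref <- rod$velocities + dense$dv
    scale <- max(abs(vref))
    expect_lt(max(abs(vref - res$rod$velocities)), 1e-10 * max(scale, 1))
    # internal impulses conserve linear momentum
    expect_lt(max(abs(colSums(res$impulses))), 1e-10 * max(abs(res$impulses), 1e-30))
  }
})

test_that("a single global solve restores a collinear stretched rod exactly", {
  p <- material_params()
  rod <- build_rod(10, 0.0099, p)     # rest 1.1 mm segments
  rod$rest_segment_length <- 0.001    # now uniformly stretched 10%
  res <- solve_distance_global(rod, dt = 1e-3, stabilization = 1)
  r <- res$rod
  r$points <- r$points + 1e-3 * r$velocities
  seg <- sqrt(rowSums(diff(r$points)^2))
  expect_lt(max(abs(seg - 0.001)), 1e-9)

  # already satisfied, at rest: identity
  ok <- build_rod(10, 0.009, p)
  res0 <- solve_distance_global(ok, dt = 1e-3, stabilization = 1)
  expect_equal(max(abs(res0$impulses)), 0, tolerance = 1e-15)

  # all points fixed: singular system reports zero impulses
  pinned <- ok
  pinned$inv_mass[] <- 0
  pinned$points[5, 1] <- pinned$points[5, 1] + 1e-4
  resp <- solve_distance_global(pinned, dt = 1e-3, stabilization = 1)
  expect_equal(max(abs(resp$impulses)), 0)
})

test_that("local sweeps: identity when satisfied, GS dominates Jacobi, log-linear decay", {
  p <- material_params()
  ok <- build_rod(12, 0.011, p)
  r0 <- iterate_distance_local(ok, "gauss_seidel", 1)
  expect_equal(max(abs(r0$impulses)), 0, tolerance = 1e-15)

  rod <- perturbed_rod(30, seed = 5)
  gs <- iterate_distance_local(rod, "gauss_seidel", 100, dt = 1e-3,
                               stabilization = 1)
  jc <- iterate_distance_local(rod, "jacobi", 100, dt = 1e-3,
                               stabilization = 1)
  expect_true(all(gs$residuals <= jc$residuals * (1 + 1e-12)))
  expect_true(all(diff(gs$residuals) <= 1e-12 * gs$residuals[1]))

  k <- 1:100
  for (res in list(gs$residuals, jc$residuals)) {
    keep <- res > res[1] * 1e-12 # above the floating-point floor
    fit <- stats::lm(log(res[keep]) ~ k[keep])
    expect_gt(summary(fit)$r.squared, 0.95)
  }
})

test_that("concentric constraints permit coaxial sliding and conserve momentum", {
  p <- material_params()
  cath <- build_rod(11, 0.01, material_params(radius = 1e-3))
  gw <- build_rod(6, 0.005, p)

  # on the catheter axis with matching velocities: no impulses
  res <- apply_concentric_constraints(gw, cath)
  expect_equal(max(abs(res$guidewire_impulses)), 0, tolerance = 1e-15)

  # pure axial sliding stays free
  slide <- gw
  slide$velocities[, 1] <- 0.05
  ress <- apply_concentric_constraints(slide, cath)
  expect_equal(max(abs(ress$guidewire_impulses)), 0, tolerance = 1e-12)

  # off-axis, lateral drift: impulses appear, are perpendicular to the
  # catheter tangent, and sum to zero with the catheter reaction
  off <- gw
  off$points[, 2] <- off$points[, 2] + 2e-4
  off$velocities[, 2] <- 0.01
  reso <- apply_concentric_constraints(off, cath, dt = 1e-3,
                                       stabilization = 0.2)
  expect_gt(max(abs(reso$guidewire_impulses)), 0)
  total <- colSums(reso$guidewire_impulses) + colSums(reso$catheter_impulses)
  expect_lt(max(abs(total)), 1e-12 * max(abs(reso$guidewire_impulses)))

  # single linked point: the impulse is exactly perpendicular to the
  # catheter tangent
  one <- build_rod(2, 1e-3, p, base_position = c(4e-3, 0, 0))
  one$points[, 2] <- one$points[, 2] + 2e-4
  one$velocities[, 2] <- 0.01
  one$inv_mass[2] <- 0 # a single dynamic linked point
  res1 <- apply_concentric_constraints(one, cath, dt = 1e-3,
                                       stabilization = 0.2)
  expect_lt(max(abs(res1$guidewire_impulses[, 1])),
            1e-12 * max(abs(res1$guidewire_impulses)))
  # a guidewire point beyond the catheter tip is left free
  beyond <- gw
  beyond$points[, 1] <- beyond$points[, 1] + 0.02 # all distal of the tip
  beyond$velocities[, 2] <- 0.01
  resb <- apply_concentric_constraints(beyond, cath)
  expect_equal(max(abs(resb$guidewire_impulses)), 0, tolerance = 1e-15)
})

test_that("a PGS step is a fixed point for an unloaded rod and projects contacts", {
  p <- material_params()
  rod <- build_rod(10, 0.009, p)
  out <- pgs_step(list(rod), config = sim_config())
  expect_equal(out$instruments[[1]]$points, rod$points, tolerance = 1e-15)
  expect_equal(out$instruments[[1]]$velocities, rod$velocities,
               tolerance = 1e-15)

  # synthetic contact set: normal impulses are never negative
  moving <- rod
  moving$velocities[4, ] <- c(0, -0.05, 0)
  contacts <- list(point_index = 4L, normal = matrix(c(0, 1, 0), 1, 3),
                   penetration_depth = 1e-4, friction_coefficient = 0.3)
  out2 <- pgs_step(list(moving), list(contacts), sim_config())
  expect_true(all(out2$normal_impulses[[1]] >= 0))
})

test_that("two-instrument PGS conserves momentum without anchors or contacts", {
  gw <- perturbed_rod(8, seed = 21)
  cath <- perturbed_rod(12, seed = 22, params = material_params(radius = 1e-3))
  p0 <- colSums(gw$mass * gw$velocities) + colSums(cath$mass * cath$velocities)
  out <- pgs_step(list(gw, cath), config = sim_config(outer_iterations = 5))
  g2 <- out$instruments[[1]]; c2 <- out$instruments[[2]]
  p1 <- colSums(g2$mass * g2$velocities) + colSums(c2$mass * c2$velocities)
  expect_lt(max(abs(p1 - p0)), 1e-10 * max(abs(p0), 1e-3))
})
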