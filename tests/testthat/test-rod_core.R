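test_that("rod construction fixes the canonical discretization", {
  p <- material_params()
  rod <- build_rod(256, 0.255, p)
  expect_equal(rod$rest_segment_length, 0.001, tolerance = 1e-12)
  expect_equal(nrow(rod$frames), 255)

  minimal <- build_rod(2, 1, p)
  expect_equal(nrow(minimal$points), 2)
  expect_equal(minimal$rest_segment_length, 1)
  expect_equal(nrow(minimal$frames), 1)

  expect_lt(max(abs(sqrt(rowSums(rod$frames^2)) - 1)), 1e-12)
  expect_error(build_rod(1, 0.1, p), "n_points")
  expect_error(build_rod(10, -1, p), "positive")
})

test_that("a straight untwisted rod at rest carries no elastic load", {
  p <- material_params()
  rod <- build_rod(12, 0.011, p)
  el <- elastic_forces(rod, p)
  pc <- parallel_constraint_forces(rod, p)
  expect_equal(max(abs(el$torque)), 0, tolerance = 1e-15)
  expect_equal(max(abs(pc$force)), 0, tolerance = 1e-12)
  expect_equal(max(abs(pc$torque)), 0, tolerance = 1e-12)
})

test_that("bending torques oppose imposed curvature", {
  p <- material_params()
  n <- 10
  rod <- build_rod(n, (n - 1) * 1e-3, p)
  # bend the frames into a circular arc about z (points left straight;
  # only the frame field carries the curvature)
  ang <- 0.1
  for (j in seq_len(n - 1)) rod <- rotate_frame(rod, j, c(0, 0, 1), (j - 1) * ang)
  el <- elastic_forces(rod, p)
  # restoring: torque on the first frame is +z (towards larger angle),
  # on the last frame -z
  expect_gt(el$torque[1, 3], 0)
  expect_lt(el$torque[n - 1, 3], 0)
})

test_that("elastic and parallel forces match finite-difference energy gradients", {
  p <- material_params()
  h <- 1e-7
  for (case in 1:20) {
    rod <- perturbed_rod(6, seed = case)
    el <- elastic_forces(rod, p)
    pc <- parallel_constraint_forces(rod, p)
    ebend <- function(r) rod_energy(r, p)$bend_twist
    epar <- function(r) rod_energy(r, p)$parallel
    j <- 1 + (case %% 4)  # frame to probe
    i <- 1 + (case %% 5)  # point to probe
    for (ax in 1:3) {
      axv <- c(0, 0, 0); axv[ax] <- 1
      fd_b <- -(ebend(rotate_frame(rod, j, axv, h)) -
                ebend(rotate_frame(rod, j, axv, -h))) / (2 * h)
      expect_lt(abs(el$torque[j, ax] - fd_b), 1e-5 * max(abs(fd_b), 1e-10))
      fd_p <- -(epar(rotate_frame(rod, j, axv, h)) -
                epar(rotate_frame(rod, j, axv, -h))) / (2 * h)
      expect_lt(abs(pc$torque[j, ax] - fd_p), 1e-5 * max(abs(fd_p), 1e-10))
      rp <- rod; rp$points[i, ax] <- rp$points[i, ax] + h
      rm <- rod; rm$points[i, ax] <- rm$points[i, ax] - h
      fd_f <- -(epar(rp) - epar(rm)) / (2 * h)
      expect_lt(abs(pc$force[i, ax] - fd_f), 1e-5 * max(abs(fd_f), 1e-8))
    }
  }
})

test_that("tip softening scales the distal bending stiffness", {
  soft <- material_params(tip_modulus_ratio = 0.2, tip_point_count = 3)
  stiff <- material_params(tip_modulus_ratio = 1, tip_point_count = 0)
  rod <- perturbed_rod(10, seed = 3, params = soft)
  t_soft <- elastic_forces(rod, soft)$torque
  t_stiff <- elastic_forces(rod, stiff)$torque
  # distal (tip-side) torques shrink, proximal ones are untouched
  expect_lt(max(abs(t_soft[1, ])), max(abs(t_stiff[1, ])))
  expect_equal(t_soft[8, ], t_stiff[8, ], tolerance = 1e-12)
})

test_that("integration is a fixed point at rest and ballistic under constant force", {
  p <- material_params()
  cfg <- sim_config(damping = 0)
  rod <- build_rod(8, 0.007, p)
  out <- integrate_step(rod, p, 1e-3, config = cfg)
  expect_equal(out$points, rod$points, tolerance = 1e-15)
  expect_equal(out$velocities, rod$velocities, tolerance = 1e-15)

  # free single segment, constant force: symplectic-Euler closed form
  seg <- build_rod(2, 0.002, p)
  Fext <- matrix(1e-3, 2, 3)
  m <- seg$mass[1]
  s <- seg
  for (k in 1:10) s <- integrate_step(s, p, 1e-3, Fext, cfg)
  n <- 10; dt <- 1e-3
  expected <- (1e-3 / m) * dt^2 * n * (n + 1) / 2
  centroid <- colMeans(s$points) - colMeans(seg$points)
  expect_equal(unname(centroid), rep(expected, 3), tolerance = 1e-9 * expected)
})

test_that("damped free dynamics dissipate energy monotonically", {
  # resolved-timestep regime: soft parameters so every mode satisfies
  # omega * dt << 1, where the implicit-damping update is monotone
  p <- material_params(young_modulus_shaft = 1e5,
                       parallel_spring_constant = 2e-3)
  cfg <- sim_config(damping = 5)
  rod <- perturbed_rod(10, seed = 7, pos_scale = 1e-4, frame_scale = 0.02,
                       params = p)
  e_prev <- rod_energy(rod, p, cfg)$total
  for (k in 1:1000) {
    rod <- integrate_step(rod, p, 1e-3, config = cfg)
    e <- rod_energy(rod, p, cfg)$total
    expect_lte(e, e_prev + 1e-10)
    e_prev <- e
  }
})

test_that("quaternions stay unit over long runs", {
  p <- material_params()
  cfg <- sim_config()
  rod <- perturbed_rod(12, seed = 9)
  sim <- simulate_insertion(rod, p, phantom = NULL, drive = NULL,
                            config = cfg, duration = 10) # 10^4 steps
  qn <- sqrt(rowSums(sim$rod$frames^2))
  expect_lt(max(abs(qn - 1)), 1e-9)
})

test_that("insertion drive feeds, twists and withdraws point by point", {
  p <- material_params()
  rod <- build_rod(21, 0.02, p, inserted_length = 0)
  rod <- advance_insertion(rod, dt = 0)
  a0 <- rod$active_count

  same <- advance_insertion(rod, dt = 0.5, push_speed = 0)
  expect_equal(same$inserted_length, rod$inserted_length)
  expect_equal(same$active_count, a0)

  # push 1 mm/s with 1-mm segments: one activation per second
  r <- rod
  for (k in 1:1000) r <- advance_insertion(r, dt = 1e-3, push_speed = 1e-3)
  expect_equal(r$active_count, a0 + 1L)

  # push then equal withdrawal returns to the initial count
  r2 <- r
  for (k in 1:1000) r2 <- advance_insertion(r2, dt = 1e-3, push_speed = -1e-3)
  expect_equal(r2$active_count, a0)
  expect_equal(r2$inserted_length, rod$inserted_length, tolerance = 1e-12)

  # withdrawal past zero clamps
  r3 <- advance_insertion(rod, dt = 10, push_speed = -1)
  expect_equal(r3$inserted_length, 0)
})

test_that("doubling K_p strengthens the restoring alignment, never weakening it", {
  # torque on a frame rotated 90 degrees off its edge scales with K_p
  torque_mag <- function(Kp) {
    p <- material_params(parallel_spring_constant = Kp)
    rod <- build_rod(5, 0.004, p)
    rod <- rotate_frame(rod, 2, c(0, 1, 0), pi / 2)
    max(abs(parallel_constraint_forces(rod, p)$torque[2, ]))
  }
  mags <- vapply(c(0.02, 0.04, 0.08, 0.16), torque_mag, numeric(1))
  expect_true(all(diff(mags) > 0))
  expect_equal(mags[2] / mags[1], 2, tolerance = 1e-9)

  # and the misalignment decay over a fixed horizon is not slowed
  mis_after <- function(Kp, steps = 30) {
    p <- material_params(parallel_spring_constant = Kp)
    cfg <- sim_config(damping = 0.5)
    rod <- perturbed_rod(8, seed = 11, frame_scale = 0.1, params = p)
    for (k in seq_len(steps)) rod <- integrate_step(rod, p, 1e-3, config = cfg)
    e <- rod$points[1:7, ] - rod$points[2:8, ]
    t_ <- e / sqrt(rowSums(e^2))
    d3 <- cbind(2 * (rod$frames[, 2] * rod$frames[, 4] + rod$frames[, 1] * rod$frames[, 3]),
                2 * (rod$frames[, 3] * rod$frames[, 4] - rod$frames[, 1] * rod$frames[, 2]),
                1 - 2 * (rod$frames[, 2]^2 + rod$frames[, 3]^2))
    max(sqrt(rowSums((d3 - t_)^2)))
  }
  expect_lte(mis_after(0.04), mis_after(0.02) + 1e-6)
})

test_that("compression metric is exact arithmetic over the active chain", {
  p <- material_params()
  rod <- build_rod(101, 0.1, p)
  expect_equal(compression_metric(rod), 0, tolerance = 1e-12)
  squeezed <- rod
  squeezed$points <- rod$points * 0.99  # arc 99 mm over 100 mm nominal
  expect_equal(compression_metric(squeezed), 1.0, tolerance = 1e-9)
})
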