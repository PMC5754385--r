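make_frames <- function(n = 4) {
  base <- small_tube(segments = 8L, axial_step = 6e-3)
  lapply(seq_len(n) - 1, function(k) {
    m <- base$mesh
    m$vertices <- m$vertices + 1e-3 * sin(2 * pi * k / n) *
      outer(rep(1, nrow(m$vertices)), c(0, 1, 0))
    m
  })
}

test_that("keyframe interpolation is exact at knots, linear and periodic", {
  anim <- keyframe_animation(make_frames(4), period = 1)
  f2 <- interpolate_keyframes(anim, 0.25)
  expect_identical(f2$vertices, anim$frames[[2]]$vertices) # bit-exact knot
  mid <- interpolate_keyframes(anim, 0.125)
  expect_equal(mid$vertices,
               (anim$frames[[1]]$vertices + anim$frames[[2]]$vertices) / 2,
               tolerance = 1e-15)
  again <- interpolate_keyframes(anim, 0.125 + 3)
  expect_equal(again$vertices, mid$vertices, tolerance = 1e-12)

  bad <- make_frames(3)
  bad[[2]]$vertices <- bad[[2]]$vertices[-1, , drop = FALSE]
  expect_error(keyframe_animation(bad, 1), "topology")
})

test_that("contrast advection conserves fill and saturates opacity", {
  n <- 12
  col <- contrast_column(cbind(seq(0, 0.033, length.out = n), 0, 0),
                         radii = 1.5e-3, flow_speed = 0.05)
  # empty system is a fixed point
  c0 <- contrast_step(col, injection_rate = 0, heart_phase = 0.3, dt = 1e-2)
  expect_equal(c0$fill, numeric(n))
  expect_equal(c0$opacity, numeric(n))

  set.seed(17)
  c1 <- col
  front_prev <- 0
  prev_out <- 0
  for (k in 1:200) {
    before <- sum(c1$fill)
    inj <- runif(1, 0, 2)
    phase <- (k * 1e-2) %% 1
    c1 <- contrast_step(c1, inj, phase, dt = 1e-2)
    delta <- sum(c1$fill) - before
    injected <- inj * 1e-2
    out_step <- c1$outflow_total - prev_out
    prev_out <- c1$outflow_total
    # conservation: fill change equals injected minus outflow this step
    expect_lt(abs(delta - (injected - out_step)), 1e-12)
    expect_true(all(c1$opacity >= 0 & c1$opacity <= 1))
    # monotone advection front
    front <- max(c(0, which(c1$fill > 1e-12)))
    expect_gte(front, front_prev)
    front_prev <- front
  }
  expect_equal(sum(c1$fill), c1$injected_total - c1$outflow_total,
               tolerance = 1e-12 * max(1, c1$injected_total))
})

test_that("balloon inflation fits the lumen and morphs the vessel persistently", {
  pair <- make_stenosed_vessel(2e-3, stenosis_center = 0.03, severity = 0.5,
                               extent = 0.012, segments = 16L)
  centres <- cbind(seq(0.022, 0.038, length.out = 8), 0, 0)
  b <- balloon_state(centres, target_radius = 2e-3)

  # inflate for 2 s: radii confined by the (morphing) stenosed wall
  res <- NULL
  for (k in 1:200) {
    res <- balloon_step(b, pair$stenosed, pair$healthy, "inflate", dt = 1e-2)
    b <- res$balloon
    clearance <- point_mesh_distance(b$positions, res$mesh)
    expect_true(all(b$radii <= clearance + 1e-9))
  }
  expect_equal(b$inflation, 1)
  expect_equal(b$morph, 1)
  # at full morph the vessel equals the healthy mesh bit-exactly
  expect_identical(res$mesh$vertices, pair$healthy$mesh$vertices)

  # deflation returns the radii but the vessel change persists
  for (k in 1:200) {
    res <- balloon_step(b, pair$stenosed, pair$healthy, "deflate", dt = 1e-2)
    b <- res$balloon
  }
  expect_equal(b$inflation, 0)
  expect_equal(b$morph, 1)
  expect_true(all(b$radii <= b$initial_radius + 1e-12))
  expect_identical(res$mesh$vertices, pair$healthy$mesh$vertices)
})

test_that("balloon radii respect clearance across random stenosis geometries", {
  set.seed(19)
  for (case in 1:20) {
    sev <- runif(1, 0.2, 0.8)
    ctr <- runif(1, 0.02, 0.04)
    ext <- runif(1, 0.006, 0.015)
    pair <- make_stenosed_vessel(2e-3, stenosis_center = ctr, severity = sev,
                                 extent = ext, segments = 12L,
                                 axial_step = 2e-3)
    b <- balloon_state(cbind(seq(ctr - 6e-3, ctr + 6e-3, length.out = 6),
                             0, 0), target_radius = 2.2e-3)
    b$inflation <- 1 # jump straight to full commanded size
    res <- balloon_step(b, pair$stenosed, pair$healthy, "inflate", dt = 1e-6)
    clearance <- point_mesh_distance(res$balloon$positions, res$mesh)
    expect_true(all(res$balloon$radii <= clearance + 1e-9))
  }
})

test_that("vessel morphing displacement is proportional to the morph parameter", {
  pair <- make_stenosed_vessel(2e-3, stenosis_center = 0.03, severity = 0.6,
                               extent = 0.01, segments = 12L)
  d_full <- pair$healthy$mesh$vertices - pair$stenosed$mesh$vertices
  for (m in c(0.25, 0.5, 0.75)) {
    V <- (1 - m) * pair$stenosed$mesh$vertices + m * pair$healthy$mesh$vertices
    expect_equal(V - pair$stenosed$mesh$vertices, m * d_full,
                 tolerance = 1e-12)
  }
})

test_that("the stent rides the balloon, anchors on release, follows vessel motion", {
  pair <- make_stenosed_vessel(2e-3, stenosis_center = 0.03, severity = 0.5,
                               extent = 0.012, segments = 16L)
  centres <- cbind(seq(0.024, 0.036, length.out = 6), 0, 0)
  b <- balloon_state(centres, target_radius = 1.9e-3)
  st <- stent_state(n_spheres = 6)

  # attachment before release
  st <- stent_release_step(st, b, pair$stenosed$mesh, dt = 1e-3)
  expect_equal(st$positions, b$positions)

  # premature release is rejected
  expect_error(stent_release(st, pair$healthy$mesh, inflation = 0.2),
               "below deployment threshold")

  st <- stent_release(st, pair$healthy$mesh, inflation = 1)
  expect_true(st$released)

  # zero vessel motion: spring forces balanced at release
  st1 <- stent_release_step(st, b, pair$healthy$mesh, dt = 1e-3)
  expect_lt(st1$spring_force_max, 1e-8)

  # rigid vessel translation: the stent centroid follows within 1 %
  tr <- c(1e-3, 5e-4, -5e-4)
  moved <- pair$healthy$mesh
  moved$vertices <- sweep(moved$vertices, 2, tr, `+`)
  c0 <- colMeans(st1$positions)
  for (k in 1:2000) st1 <- stent_release_step(st1, b, moved, dt = 1e-3)
  shift <- colMeans(st1$positions) - c0
  expect_lt(max(abs(shift - tr)), 0.01 * sqrt(sum(tr^2)))
})
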