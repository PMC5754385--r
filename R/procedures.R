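# Angioplasty supporting models: contrast propagation through an ordered
# sphere chain, balloon inflation with stenosed->healthy vessel morphing,
# stent deployment anchored by a mass-spring model, and keyframe cardiac
# motion.

#' Keyframe mesh animation
#'
#' @param frames List of same-topology [triangle_mesh()] keyframes (the
#'   canonical cardiac cycle uses 24).
#' @param period Cycle period (s).
#' @return A `keyframe_animation`.
#' @export
keyframe_animation <- function(frames, period) {
  stopifnot(length(frames) >= 2, period > 0)
  nv <- nrow(frames[[1]]$vertices)
  nf <- nrow(frames[[1]]$faces)
  for (f in frames)
    if (nrow(f$vertices) != nv || nrow(f$faces) != nf)
      stop("keyframes must share topology")
  out <- list(frames = frames, period = period)
  class(out) <- "keyframe_animation"
  out
}

#' Interpolate the animated mesh at a given time
#'
#' Linear vertex interpolation between the two bracketing keyframes,
#' cyclic in the period. At exact frame instants the keyframe is returned
#' bit-exactly. The output feeds [refit_aabb_tree()].
#'
#' @param animation A [keyframe_animation()].
#' @param time Query time (s).
#' @return A [triangle_mesh()].
#' @export
interpolate_keyframes <- function(animation, time) {
  n <- length(animation$frames)
  fd <- animation$period / n
  k <- (time %% animation$period) / fd
  i0 <- floor(k + 1e-9)
  u <- k - i0
  i0 <- i0 %% n
  if (abs(u) < 1e-9) return(animation$frames[[i0 + 1]])
  i1 <- (i0 + 1) %% n
  V <- (1 - u) * animation$frames[[i0 + 1]]$vertices +
       u * animation$frames[[i1 + 1]]$vertices
  triangle_mesh(V, animation$frames[[i0 + 1]]$faces)
}

#' Contrast medium column
#'
#' An ordered chain of spheres fitted along a coronary centreline; each
#' sphere carries its index, position, radius and pre-calculated flow
#' speed. Contrast fill is advected down the chain and rendered as
#' opacity.
#'
#' @param positions n x 3 sphere centres (m), ordered along the vessel.
#' @param radii Sphere radii (m).
#' @param flow_speed Per-sphere flow speed (m/s).
#' @return A `contrast_column` with zero fill.
#' @export
contrast_column <- function(positions, radii, flow_speed) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  radii <- rep_len(radii, n); flow_speed <- rep_len(flow_speed, n)
  spacing <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                           positions[-n, , drop = FALSE])^2))
  out <- list(positions = positions, radii = radii, flow_speed = flow_speed,
              spacing = c(spacing, spacing[length(spacing)]),
              fill = numeric(n), opacity = numeric(n),
              injected_total = 0, outflow_total = 0)
  class(out) <- "contrast_column"
  out
}

#' Advance contrast propagation by one step
#'
#' Conservative upwind advection of fill down the sphere chain at the
#' per-sphere flow speed scaled by a heartbeat-phase factor
#' `1 + amplitude * sin(2 pi phase)`; injection adds fill at the first
#' sphere and fill leaving the last sphere is accounted as outflow.
#' Opacity is the fill scaled inversely with sphere volume, clamped to
#' \[0, 1\].
#'
#' @param column A [contrast_column()].
#' @param injection_rate Contrast injection rate (fill/s), >= 0.
#' @param heart_phase Cardiac phase in \[0, 1).
#' @param dt Time step (s), > 0.
#' @param amplitude Phase-modulation amplitude of the flow speed.
#' @param opacity_scale Fill amount saturating one unit of sphere volume.
#' @param decay Optional washout rate (1/s), default none.
#' @return The updated column (fields `fill`, `opacity`,
#'   `injected_total`, `outflow_total`).
#' @export
contrast_step <- function(column, injection_rate, heart_phase, dt,
                          amplitude = 0.5, opacity_scale = 1e6, decay = 0) {
  stopifnot(dt > 0, injection_rate >= 0)
  phase_factor <- 1 + amplitude * sin(2 * pi * heart_phase)
  frac <- pmin(1, phase_factor * column$flow_speed * dt / column$spacing)
  moved <- column$fill * frac
  fill <- column$fill - moved
  n <- length(fill)
  fill[-1] <- fill[-1] + moved[-n]
  outflow <- moved[n]
  injected <- injection_rate * dt
  fill[1] <- fill[1] + injected
  if (decay > 0) {
    lost <- fill * (1 - exp(-decay * dt))
    fill <- fill - lost
    outflow <- outflow + sum(lost)
  }
  column$fill <- fill
  column$injected_total <- column$injected_total + injected
  column$outflow_total <- column$outflow_total + outflow
  vol <- (4 / 3) * pi * column$radii^3
  column$opacity <- pmin(1, pmax(0, fill / (opacity_scale * vol)))
  column
}

#' Balloon state attached to the distal guidewire
#'
#' @param positions n x 3 sphere centres along the distal guidewire (m);
#'   the default geometry uses 8 spheres over the distal 16 mm.
#' @param target_radius Fully inflated sphere radius (m).
#' @param initial_radius Deflated radius (m).
#' @return A `balloon_state` with `inflation = morph = 0`.
#' @export
balloon_state <- function(positions, target_radius,
                          initial_radius = 0.2e-3) {
  positions <- as.matrix(positions)
  out <- list(positions = positions,
              radii = rep(initial_radius, nrow(positions)),
              initial_radius = initial_radius,
              target_radius = target_radius,
              inflation = 0, morph = 0)
  class(out) <- "balloon_state"
  out
}

#' Inflate or deflate the balloon, morphing the vessel
#'
#' Inflation ramps linearly over `inflate_time`; sphere radii grow toward
#' the target but are clipped by iterative collision against the current
#' morphed vessel surface, so they never exceed the local clearance. The
#' vessel morph (stenosed -> healthy vertex interpolation) ratchets with
#' the maximum inflation reached, making the treatment persistent after
#' deflation.
#'
#' @param balloon A [balloon_state()].
#' @param stenosed,healthy Same-topology `tube_phantom` or
#'   [triangle_mesh()] pair.
#' @param command `"inflate"` or `"deflate"`.
#' @param dt Time step (s).
#' @param inflate_time Full inflation duration (s).
#' @param tolerance Contact tolerance (m) left between sphere and wall.
#' @return List with the updated `balloon` and the morphed `mesh`.
#' @export
balloon_step <- function(balloon, stenosed, healthy,
                         command = c("inflate", "deflate"), dt,
                         inflate_time = 2, tolerance = 1e-5) {
  command <- match.arg(command)
  sm <- if (inherits(stenosed, "tube_phantom")) stenosed$mesh else stenosed
  hm <- if (inherits(healthy, "tube_phantom")) healthy$mesh else healthy
  if (nrow(sm$vertices) != nrow(hm$vertices) ||
      nrow(sm$faces) != nrow(hm$faces))
    stop("stenosed and healthy meshes must share topology")
  dir <- if (command == "inflate") 1 else -1
  balloon$inflation <- min(1, max(0, balloon$inflation + dir * dt / inflate_time))
  balloon$morph <- max(balloon$morph, balloon$inflation)
  V <- (1 - balloon$morph) * sm$vertices + balloon$morph * hm$vertices
  mesh <- triangle_mesh(V, sm$faces)
  want <- balloon$initial_radius +
    (balloon$target_radius - balloon$initial_radius) * balloon$inflation
  clearance <- point_mesh_distance(balloon$positions, mesh)
  balloon$radii <- pmin(want, pmax(clearance - tolerance, 0))
  list(balloon = balloon, mesh = mesh)
}

#' Stent state
#'
#' Spheres riding on the balloon until release; afterwards a mass-spring
#' model anchored to the vessel surface keeps the stent in place and
#' makes it follow vessel motion.
#'
#' @param n_spheres Number of stent spheres.
#' @param mass Sphere mass (kg).
#' @param settle_time Target anchor settling time (s); sets the spring
#'   stiffness, with critical damping.
#' @return A `stent_state` (unreleased).
#' @export
stent_state <- function(n_spheres = 8L, mass = 1e-4, settle_time = 0.5) {
  omega <- 4.6 / settle_time # exp(-4.6) ~ 1% residual at settle_time
  out <- list(positions = matrix(0, n_spheres, 3),
              velocities = matrix(0, n_spheres, 3),
              radii = numeric(n_spheres),
              mass = mass,
              stiffness = mass * omega^2,
              damping = 2 * mass * omega,
              released = FALSE, anchors = NULL)
  class(out) <- "stent_state"
  out
}

#' Release the stent, anchoring it to the vessel wall
#'
#' @param stent A `stent_state` currently tracking the balloon.
#' @param vessel A [triangle_mesh()] (current morphed vessel).
#' @param inflation Current balloon inflation; release requires >= 0.5.
#' @return The released `stent_state` with immutable anchors (per sphere,
#'   its nearest vessel vertices and rest offset vectors).
#' @export
stent_release <- function(stent, vessel, inflation) {
  if (stent$released) stop("stent already released")
  if (inflation < 0.5)
    stop("stent release rejected: balloon inflation ", inflation,
         " below deployment threshold 0.5")
  anchors <- vector("list", nrow(stent$positions))
  for (i in seq_len(nrow(stent$positions))) {
    d2 <- colSums((t(vessel$vertices) - stent$positions[i, ])^2)
    vi <- order(d2)[1:3]
    # vector springs: rest offsets from the anchor vertices, so the
    # sphere is pinned isotropically and follows wall motion rigidly
    anchors[[i]] <- list(
      vertex = vi,
      offset = sweep(-vessel$vertices[vi, , drop = FALSE], 2,
                     stent$positions[i, ], `+`))
  }
  stent$anchors <- anchors
  stent$released <- TRUE
  stent
}

#' Advance the stent by one step
#'
#' Before release the stent copies the balloon sphere poses; after
#' release the anchor springs (rest lengths frozen at release) pull each
#' sphere with the moving vessel wall under critically damped dynamics.
#'
#' @param stent A `stent_state`.
#' @param balloon The [balloon_state()] it rides on (pre-release).
#' @param vessel Current vessel [triangle_mesh()].
#' @param dt Time step (s).
#' @return The updated `stent_state`; `$spring_force_max` reports the
#'   largest residual spring force (N).
#' @export
stent_release_step <- function(stent, balloon, vessel, dt) {
  if (!stent$released) {
    stent$positions <- balloon$positions
    stent$radii <- balloon$radii
    stent$spring_force_max <- 0
    return(stent)
  }
  fmax <- 0
  for (i in seq_len(nrow(stent$positions))) {
    a <- stent$anchors[[i]]
    F <- c(0, 0, 0)
    for (k in seq_along(a$vertex)) {
      target <- vessel$vertices[a$vertex[k], ] + a$offset[k, ]
      F <- F + stent$stiffness * (target - stent$positions[i, ])
    }
    F <- F - stent$damping * stent$velocities[i, ]
    fmax <- max(fmax, sqrt(sum(F^2)))
    stent$velocities[i, ] <- stent$velocities[i, ] + dt * F / stent$mass
    stent$positions[i, ] <- stent$positions[i, ] + dt * stent$velocities[i, ]
  }
  stent$spring_force_max <- fmax
  stent
}
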