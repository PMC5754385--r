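#' Build a straight discrete rod
#'
#' Discretizes an instrument of length `total_length` into `n_points` mass
#' points connected by `n_points - 1` edges. Each edge carries a material
#' frame (a unit quaternion) whose third director equals the edge tangent,
#' the discrete form of a Cosserat rod centreline with adapted frames.
#' The rod is built straight along `base_axis` with its distal tip at
#' `base_position + inserted_length * base_axis` and zero velocities.
#'
#' @param n_points Number of mass points (>= 2). Point 1 is the distal tip.
#' @param total_length Rod length (m).
#' @param params [material_params()] for the instrument (sets point masses).
#' @param base_position Insertion/base point (length-3, m).
#' @param base_axis Unit insertion axis; the rod lies along it.
#' @param inserted_length Arc length of rod past the base point (m).
#'   Defaults to the whole rod (a free, fully dynamic rod). Use
#'   [advance_insertion()] to feed a partially inserted rod.
#' @param rest_darboux Optional (n_points - 2) x 3 matrix of intrinsic
#'   Darboux vectors (rad/m) for shaped instruments; default straight.
#' @return An object of class `rod_state`.
#' @examples
#' rod <- build_rod(256, 0.255, material_params())
#' rod$rest_segment_length # 0.001 m
#' @export
build_rod <- function(n_points, total_length, params,
                      base_position = c(0, 0, 0),
                      base_axis = c(1, 0, 0),
                      inserted_length = total_length,
                      rest_darboux = NULL) {
  n_points <- as.integer(n_points)
  if (n_points < 2) stop("n_points must be >= 2")
  if (!is.numeric(total_length) || total_length <= 0)
    stop("total_length must be positive")
  validate_material_params(params)
  axis <- base_axis / sqrt(sum(base_axis^2))
  l0 <- total_length / (n_points - 1)
  s <- min(max(inserted_length, 0), total_length)
  arc <- (seq_len(n_points) - 1) * l0        # arc offset from the tip
  pts <- cbind(base_position[1] + (s - arc) * axis[1],
               base_position[2] + (s - arc) * axis[2],
               base_position[3] + (s - arc) * axis[3])
  q <- frame_from_tangent(axis)
  ne <- n_points - 1L
  m <- params$density * pi * params$radius^2 * l0
  if (is.null(rest_darboux)) {
    rest_darboux <- matrix(0, max(n_points - 2L, 0L), 3)
  } else {
    rest_darboux <- as.matrix(rest_darboux)
    stopifnot(nrow(rest_darboux) == n_points - 2L, ncol(rest_darboux) == 3)
  }
  rod <- list(points = pts,
              velocities = matrix(0, n_points, 3),
              frames = matrix(rep(q, each = ne), ne, 4),
              angular_velocities = matrix(0, ne, 3),
              mass = rep(m, n_points),
              inv_mass = rep(1 / m, n_points),
              rest_segment_length = l0,
              inserted_length = s,
              active_count = n_points,
              rest_darboux = rest_darboux,
              entry = as.numeric(base_position),
              axis = axis,
              twist_angle = 0)
  class(rod) <- "rod_state"
  rod
}

# quaternion (w,x,y,z) of an orthonormal frame whose third director is `t`
frame_from_tangent <- function(t) {
  t <- t / sqrt(sum(t^2))
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  d1 <- pracma_cross(ref, t); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- pracma_cross(t, d1)
  rotation_to_quat(cbind(d1, d2, t))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    S <- sqrt(tr + 1) * 2
    q <- c(0.25 * S, (R[3, 2] - R[2, 3]) / S, (R[1, 3] - R[3, 1]) / S,
           (R[2, 1] - R[1, 2]) / S)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    S <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / S, 0.25 * S, (R[1, 2] + R[2, 1]) / S,
           (R[1, 3] + R[3, 1]) / S)
  } else if (R[2, 2] > R[3, 3]) {
    S <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / S, (R[1, 2] + R[2, 1]) / S, 0.25 * S,
           (R[2, 3] + R[3, 2]) / S)
  } else {
    S <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / S, (R[1, 3] + R[3, 1]) / S,
           (R[2, 3] + R[3, 2]) / S, 0.25 * S)
  }
  q / sqrt(sum(q^2))
}

#' @export
print.rod_state <- function(x, ...) {
  cat(sprintf("Discrete rod: %d points (%d active), segment %.3g mm, inserted %.1f mm\n",
              nrow(x$points), x$active_count, 1e3 * x$rest_segment_length,
              1e3 * x$inserted_length))
  invisible(x)
}

#' Elastic bending/twisting forces and torques
#'
#' Evaluates the restoring generalized forces of the discrete elastic
#' energy: for every pair of adjacent material frames the discrete Darboux
#' vector measures bending (components 1, 2) and twist (component 3), each
#' penalized by the corresponding stiffness (E I for bending, G J for
#' twist, with the distal tip softened by `tip_modulus_ratio`). Forces and
#' torques are the negative gradient of that energy; a straight, untwisted
#' rod at rest yields zeros.
#'
#' @param rod A [build_rod()] state.
#' @param params [material_params()].
#' @return List with `force` (n x 3, zero here: bending acts on frames and
#'   reaches the centreline through the parallel constraint) and `torque`
#'   ((n-1) x 3) per frame.
#' @export
elastic_forces <- function(rod, params) {
  out <- cpp_rod_forces(rod, params, as_cpp_config(sim_config()),
                        bend = TRUE, parallel = FALSE, stretch = FALSE)
  out
}

#' Parallel-constraint penalty forces and torques
#'
#' The CoRdE parallel constraint couples each frame's third director to
#' the unit edge vector through a quadratic penalty energy weighted by
#' K_p; its negative gradient yields forces on the two edge endpoints and
#' a torque on the frame, vanishing when director and edge are aligned.
#'
#' @inheritParams elastic_forces
#' @return List with `force` (n x 3) and `torque` ((n-1) x 3).
#' @export
parallel_constraint_forces <- function(rod, params) {
  cpp_rod_forces(rod, params, as_cpp_config(sim_config()),
                 bend = FALSE, parallel = TRUE, stretch = FALSE)
}

#' Energy audit of a rod state
#'
#' @inheritParams elastic_forces
#' @param config A [sim_config()] (the stretch penalty term is only
#'   counted in penalty mode).
#' @return List with components `bend_twist`, `parallel`,
#'   `stretch_penalty`, `kinetic` and `total` (J).
#' @export
rod_energy <- function(rod, params, config = sim_config()) {
  cpp_rod_energy(rod, params, as_cpp_config(config))
}

#' Advance the rod state by one explicit time step
#'
#' Semi-implicit (symplectic) Euler: internal elastic and parallel
#' constraint forces (plus, in penalty mode, the stretch penalty) and any
#' external forces update velocities first, then positions; frame
#' quaternions are advanced from angular velocities and renormalized.
#' Viscous mass-proportional damping is applied implicitly.
#'
#' @inheritParams rod_energy
#' @param dt Time step (s), > 0.
#' @param external_forces Optional n x 3 matrix of forces (N) per point.
#' @return The updated `rod_state`.
#' @export
integrate_step <- function(rod, params, dt, external_forces = NULL,
                           config = sim_config()) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(external_forces)) external_forces <- matrix(0, 0, 3)
  out <- cpp_integrate_step(rod, params, as_cpp_config(config),
                            external_forces, dt)
  class(out) <- "rod_state"
  out
}

#' Piecewise-constant insertion drive
#'
#' @param time Strictly increasing vector of times (s) at which the drive
#'   changes; must start at 0.
#' @param push_speed Push (+) / pull (-) speed (m/s) from each time on.
#' @param twist_speed Twist speed (rad/s) about the insertion axis.
#' @return An `insertion_drive` object (a schedule matrix).
#' @export
insertion_drive <- function(time = 0, push_speed = 0, twist_speed = 0) {
  k <- max(length(time), length(push_speed), length(twist_speed))
  time <- rep_len(time, k); push_speed <- rep_len(push_speed, k)
  twist_speed <- rep_len(twist_speed, k)
  if (any(diff(time) <= 0)) stop("schedule times must be strictly increasing")
  if (!all(is.finite(c(time, push_speed, twist_speed))))
    stop("schedule speeds must be finite")
  out <- cbind(time = time, push_speed = push_speed, twist_speed = twist_speed)
  class(out) <- c("insertion_drive", class(out))
  out
}

drive_at <- function(drive, t) {
  i <- findInterval(t + 1e-12, drive[, 1])
  if (i < 1) return(c(0, 0))
  c(drive[i, 2], drive[i, 3])
}

#' Feed or withdraw the rod through the insertion point
#'
#' The proximal boundary is kinematic: the first not-yet-inserted point
#' (the driver) moves along the insertion axis at `push_speed` and twists
#' at `twist_speed`; points behind it are parked on the axis. A mass point
#' is (de)activated whenever the inserted length crosses a multiple of the
#' rest segment length. Withdrawal past zero clamps at zero inserted
#' length.
#'
#' @param rod A `rod_state` attached to an insertion site (see
#'   [build_rod()] `base_position`/`base_axis`).
#' @param drive An [insertion_drive()]; alternatively pass scalar
#'   `push_speed`/`twist_speed`.
#' @param dt Time step (s).
#' @param t Current time (s), used to look up the schedule.
#' @param push_speed,twist_speed Direct speeds, used when `drive` is NULL.
#' @return Updated `rod_state`.
#' @export
advance_insertion <- function(rod, drive = NULL, dt, t = 0,
                              push_speed = 0, twist_speed = 0) {
  if (!is.null(drive)) {
    sp <- drive_at(drive, t)
    push_speed <- sp[1]; twist_speed <- sp[2]
  }
  out <- cpp_advance_insertion(rod, push_speed, twist_speed, dt)
  class(out) <- "rod_state"
  out
}

#' Rod compression as a percentage of nominal length
#'
#' 100 * (nominal length of the active portion - current arc length) /
#' nominal length. Positive values indicate compression; negative values
#' stretch.
#'
#' @param rod A `rod_state`.
#' @return Percent compression (scalar).
#' @export
compression_metric <- function(rod) {
  cpp_compression_percent(rod)
}
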