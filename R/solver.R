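#' Solver and integration configuration
#'
#' Settings of the per-step pipeline: explicit force integration followed
#' by a block-iterative Projected Gauss-Seidel (PGS) pass whose phases are
#' (1) the inextensibility distance-constraint chain, (2) concentric
#' guidewire-in-catheter constraints, (3) vessel contacts with Coulomb
#' friction. Each outer iteration re-linearizes the nonlinear constraints
#' at predicted positions.
#'
#' @param dt Physics time step (s).
#' @param damping Mass-proportional viscous damping rate (s^-1).
#' @param gravity Gravity vector (m s^-2); off by default (instruments in
#'   vessels are near-neutrally buoyant).
#' @param stabilization Baumgarte factor in \[0, 1\] converting positional
#'   constraint violation into a corrective velocity bias, used by the
#'   contact and concentric phases.
#' @param stabilization_distance Stabilization for the distance phase;
#'   the default 1 makes each solver iteration target exact satisfaction
#'   of the segment-length constraints at the end of the step.
#' @param distance_mode One of `"global_tridiagonal"` (exact direct solve
#'   of the whole chain), `"local_gauss_seidel"`, `"local_jacobi"`
#'   (iterative per-constraint sweeps) or `"penalty"` (stretch springs, the
#'   extensible baseline).
#' @param distance_iterations Sweeps per distance phase for local modes.
#' @param outer_iterations PGS outer iterations per step.
#' @param contact_iterations Gauss-Seidel sweeps over contacts.
#' @param penalty_stiffness Stretch spring constant (N/m) used in penalty
#'   mode; see [tune_penalty_stiffness()].
#' @param inertia_safety Regularization factor for the material-frame
#'   rotational inertia (kept large enough for the chosen `dt`).
#' @return A `solver_config` list.
#' @export
sim_config <- function(dt = 1e-3,
                       damping = 0.5,
                       gravity = c(0, 0, 0),
                       stabilization = 0.2,
                       stabilization_distance = 1,
                       distance_mode = c("global_tridiagonal",
                                         "local_gauss_seidel",
                                         "local_jacobi", "penalty"),
                       distance_iterations = 1L,
                       outer_iterations = 1L,
                       contact_iterations = 10L,
                       penalty_stiffness = 0,
                       inertia_safety = 4) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(dt > 0, damping >= 0, stabilization >= 0, stabilization <= 1,
            distance_iterations >= 1, outer_iterations >= 1,
            contact_iterations >= 1)
  stopifnot(stabilization_distance >= 0, stabilization_distance <= 1)
  out <- list(dt = dt, damping = damping, gravity = gravity,
              stabilization = stabilization,
              stabilization_distance = stabilization_distance,
              distance_mode = distance_mode,
              distance_iterations = as.integer(distance_iterations),
              outer_iterations = as.integer(outer_iterations),
              contact_iterations = as.integer(contact_iterations),
              penalty_stiffness = penalty_stiffness,
              inertia_safety = inertia_safety)
  class(out) <- "solver_config"
  out
}

mode_code <- c(global_tridiagonal = 0L, local_gauss_seidel = 1L,
               local_jacobi = 2L, penalty = 3L)

as_cpp_config <- function(config) {
  config$distance_mode <- mode_code[[config$distance_mode]]
  unclass(config)
}

#' Assemble the tridiagonal inextensibility system
#'
#' One equality constraint per segment keeps each edge at its rest length.
#' Arranged along the chain, the constraint Schur complement J M^-1 J^T is
#' a symmetric tridiagonal banded matrix: the diagonal holds the summed
#' inverse masses of each segment's endpoints and the off-diagonal couples
#' neighbouring segments through the dot product of their unit directions.
#' The right-hand side combines the current violation rate with a
#' Baumgarte bias proportional to the positional violation.
#'
#' @param rod A `rod_state` with at least one segment.
#' @param dt Time step (s) used for the Baumgarte bias and prediction.
#' @param stabilization Baumgarte factor (defaults to full correction,
#'   which makes a single solve + position update restore rest lengths
#'   exactly for collinear rods).
#' @param predicted Linearize at predicted positions `x + dt v` (as inside
#'   the solver loop) rather than current positions.
#' @return List with `diagonal`, `off_diagonal`, `directions`,
#'   `violation`, `violation_rate` and `rhs`.
#' @export
assemble_distance_system <- function(rod, dt = 1e-3, stabilization = 1,
                                     predicted = FALSE) {
  if (rod$active_count < 2) stop("rod must have at least one segment")
  cpp_assemble_distance(rod, dt, stabilization, predicted)
}

#' Exact global solve of the distance-constraint chain
#'
#' Direct (Thomas) solve of the tridiagonal system: all distance
#' constraints at once, as the first phase of each solver iteration. The
#' resulting velocity corrections zero the segment-length violation rates
#' at the linearization point and, being internal equal-and-opposite
#' impulses, conserve the rod's linear momentum.
#'
#' @inheritParams assemble_distance_system
#' @return List with the corrected `rod` and the per-point `impulses`
#'   (kg m/s). A fully fixed rod yields zero impulses.
#' @export
solve_distance_global <- function(rod, dt = 1e-3, stabilization = 1) {
  out <- cpp_solve_distance_global(rod, dt, stabilization)
  class(out$rod) <- "rod_state"
  out
}

#' Local Gauss-Seidel / Jacobi sweeps over distance constraints
#'
#' Sequential (Gauss-Seidel: each constraint immediately sees previous
#' updates) or accumulate-then-apply (Jacobi) sweeps over the individual
#' segment constraints.
#'
#' @inheritParams assemble_distance_system
#' @param mode `"gauss_seidel"` or `"jacobi"`.
#' @param iterations Number of sweeps (>= 1).
#' @return List with the corrected `rod`, `impulses`, and the RMS
#'   constraint `residuals` after each sweep.
#' @export
iterate_distance_local <- function(rod, mode = c("gauss_seidel", "jacobi"),
                                   iterations = 1L, dt = 1e-3,
                                   stabilization = 1) {
  mode <- match.arg(mode)
  stopifnot(iterations >= 1)
  out <- cpp_iterate_distance_local(rod, mode, as.integer(iterations), dt,
                                    stabilization)
  class(out$rod) <- "rod_state"
  out
}

#' Concentric guidewire-in-catheter constraints
#'
#' Every dynamic guidewire point alongside the catheter is linked to its
#' nearest catheter segment. Impulses act strictly perpendicular to the
#' catheter tangent (coaxial sliding stays free) and drive the
#' perpendicular relative velocity, plus a stabilization share of the
#' perpendicular offset, to zero. The equal-and-opposite reaction is split
#' between the two segment endpoints with weights (1 - w, w) given by the
#' barycentric location of the nearest point, so total linear momentum is
#' conserved. Guidewire points beyond the catheter tip are free.
#'
#' @param guidewire,catheter `rod_state` objects.
#' @param dt Time step (s).
#' @param stabilization Baumgarte factor.
#' @return List with updated `guidewire` and `catheter` plus the applied
#'   per-point impulse matrices.
#' @export
apply_concentric_constraints <- function(guidewire, catheter, dt = 1e-3,
                                         stabilization = 0.2) {
  out <- cpp_concentric_constraints(guidewire, catheter, dt, stabilization)
  class(out$guidewire) <- "rod_state"
  class(out$catheter) <- "rod_state"
  out
}

#' One block-iterative Projected Gauss-Seidel step
#'
#' Applies, for each outer iteration: the distance phase (per
#' `distance_mode`), the concentric phase (when two instruments are given,
#' in the order guidewire then catheter), and the contact phase with
#' projected non-negative normal impulses and Coulomb friction. Positions
#' are then updated from the corrected velocities. Forces must already be
#' integrated into the tentative velocities.
#'
#' @param instruments A list of `rod_state` objects (guidewire first).
#' @param contacts A list (parallel to `instruments`) of contact sets as
#'   returned by [narrow_phase_contacts()], or NULL entries.
#' @param config A [sim_config()].
#' @param dt Time step (s).
#' @return List with updated `instruments` and accumulated
#'   `normal_impulses` / `tangential_impulses` per instrument.
#' @export
pgs_step <- function(instruments, contacts = NULL, config = sim_config(),
                     dt = config$dt) {
  if (is.null(contacts)) contacts <- vector("list", length(instruments))
  out <- cpp_pgs_step(instruments, contacts, as_cpp_config(config), dt)
  out$instruments <- lapply(out$instruments, function(r) {
    class(r) <- "rod_state"; r
  })
  out
}
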