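#' Run a full insertion simulation
#'
#' Drives a rod through the per-step pipeline (insertion kinematics,
#' explicit force integration, contact detection, block-iterative PGS,
#' position update) in compiled code. Optionally continues after the
#' drive schedule with zero drive until the rod settles below a speed
#' tolerance.
#'
#' @param rod A `rod_state` positioned at its insertion site.
#' @param params [material_params()].
#' @param phantom A `tube_phantom`, a [triangle_mesh()], or NULL for free
#'   space.
#' @param drive An [insertion_drive()] schedule, or NULL for no drive.
#' @param config A [sim_config()].
#' @param duration Simulated drive time (s).
#' @param record_stride Record a trace every this many steps (0 = none).
#' @param settle_tol Continue with zero drive until the maximum point
#'   speed (m/s) drops below this (0 = no settling phase).
#' @param settle_max_steps Cap on settling steps.
#' @param fat_margin AABB fat margin; defaults to twice the instrument
#'   radius (a bound on one-step motion at intended speeds).
#' @return A `rod_sim` result: final `rod`, step counts, final
#'   compression/segment-error/contact diagnostics and the recorded
#'   `trace`.
#' @export
simulate_insertion <- function(rod, params, phantom = NULL, drive = NULL,
                               config = sim_config(), duration,
                               record_stride = 0L, settle_tol = 0,
                               settle_max_steps = 20000L,
                               fat_margin = 2 * params$radius) {
  treeptr <- NULL
  if (!is.null(phantom)) {
    mesh <- if (inherits(phantom, "tube_phantom")) phantom$mesh else phantom
    treeptr <- build_aabb_tree(mesh, fat_margin)$ptr
  }
  schedule <- if (is.null(drive)) matrix(0, 0, 3) else unclass(drive)
  out <- cpp_sim_run(rod, params, as_cpp_config(config), treeptr,
                     schedule, duration, as.integer(record_stride),
                     settle_tol, as.integer(settle_max_steps))
  class(out$rod) <- "rod_state"
  class(out) <- "rod_sim"
  out
}

#' @export
print.rod_sim <- function(x, ...) {
  cat(sprintf(
    "Rod simulation: %d steps (%d settling), compression %.3f%%, max segment error %.3g mm\n",
    as.integer(x$steps), as.integer(x$settle_steps),
    x$final_compression_percent, 1e3 * x$final_max_segment_error))
  invisible(x)
}

#' Largest stable stretch-penalty stiffness
#'
#' The extensible baseline replaces the distance-constraint chain by
#' stretch springs; its honest best case uses the largest spring constant
#' the explicit integrator tolerates. Bisection over the stiffness with a
#' fixed-length stability probe: a uniformly pre-stretched rod is
#' integrated for `probe_steps` steps and the candidate passes if the
#' state stays finite and the stretch energy does not grow. Deterministic.
#'
#' @param rod A representative `rod_state` (the probe perturbs a copy).
#' @param params [material_params()].
#' @param config A [sim_config()]; `dt` and `damping` matter.
#' @param probe_steps Steps per stability probe.
#' @param bisection_steps Bisection refinement count.
#' @return The stiffness (N/m).
#' @export
tune_penalty_stiffness <- function(rod, params, config = sim_config(),
                                   probe_steps = 1000L,
                                   bisection_steps = 18L) {
  n <- min(nrow(rod$points), 32L)
  l0 <- rod$rest_segment_length
  probe_rod <- build_rod(n, (n - 1) * l0, params)
  # deterministic broadband perturbation exciting the stiffest chain modes
  k <- seq_len(n)
  pert <- 0.05 * l0 * cbind(sin(2.7 * k) * cos(0.5 * k),
                            sin(1.3 * k + 1), cos(3.1 * k))
  probe_rod$points <- probe_rod$points + pert
  cfg <- config
  cfg$distance_mode <- "penalty"
  stable <- function(ks) {
    cfg$penalty_stiffness <- ks
    e0 <- rod_energy(probe_rod, params, cfg)$total
    res <- tryCatch(
      cpp_sim_run(probe_rod, params, as_cpp_config(cfg), NULL,
                  matrix(0, 0, 3), probe_steps * cfg$dt, 0L, 0, 0L),
      error = function(e) NULL)
    if (is.null(res)) return(FALSE)
    rend <- res$rod; class(rend) <- "rod_state"
    efin <- tryCatch(rod_energy(rend, params, cfg)$total, error = function(e) Inf)
    is.finite(efin) && efin <= e0
  }
  m <- min(rod$mass)
  hi <- 4 * m / config$dt^2      # beyond the explicit stability limit
  # descend a geometric ladder to a stable seed (very low stiffness is
  # itself unstable: nothing then maintains segment spacing)
  lo <- NA_real_
  cand <- hi / 2^seq_len(24)
  for (i in seq_along(cand)) {
    if (stable(cand[i])) {
      lo <- cand[i]
      hi <- if (i > 1) cand[i - 1] else hi
      break
    }
  }
  if (!is.finite(lo)) stop("penalty stability probe found no stable stiffness")
  for (i in seq_len(bisection_steps)) {
    mid <- sqrt(lo * hi)
    if (stable(mid)) lo <- mid else hi <- mid
  }
  lo
}
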