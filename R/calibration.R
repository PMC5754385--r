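#' Reference instrument centreline
#'
#' An ordered 3-D polyline (e.g. a scanned instrument centreline) used as
#' the calibration oracle.
#'
#' @param points n x 3 matrix of polyline vertices (m), n >= 2,
#'   consecutive points distinct.
#' @return A `reference_centreline` with cached arc-length
#'   parameterization.
#' @export
reference_centreline <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("centreline needs at least 2 points")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("consecutive centreline points must be distinct")
  out <- list(points = points, arc = c(0, cumsum(seg)))
  class(out) <- "reference_centreline"
  out
}

#' @export
print.reference_centreline <- function(x, ...) {
  cat(sprintf("Reference centreline: %d points, length %.1f mm\n",
              nrow(x$points), 1e3 * max(x$arc)))
  invisible(x)
}

#' Nearest Euclidean distance to a reference centreline
#'
#' Exact distance to the polyline, including segment interiors.
#'
#' @param points A length-3 position or an n x 3 matrix (m).
#' @param reference A [reference_centreline()].
#' @return Distance(s) in the same units.
#' @export
min_dist <- function(points, reference) {
  if (is.null(dim(points))) points <- matrix(points, 1, 3)
  cpp_min_dist_polyline(as.matrix(points), reference$points)
}

#' RMS centreline distance (calibration objective)
#'
#' The root of the mean squared nearest distance between the N simulated
#' mass points inserted into the phantom and the reference centreline:
#' f = sqrt(1/N * sum_i minDist(p_i)^2). Points outside the phantom lumen
#' are excluded from N.
#'
#' @param simulated_points n x 3 matrix of simulated mass point positions
#'   (m).
#' @param reference A [reference_centreline()].
#' @param phantom Optional `tube_phantom`; when given, only points inside
#'   its lumen (within `inner_radius` of the analytic centreline and
#'   within its arc extent) count.
#' @return RMS distance (same units as the inputs).
#' @export
rms_error <- function(simulated_points, reference, phantom = NULL) {
  pts <- as.matrix(simulated_points)
  if (!is.null(phantom)) {
    memb <- tube_centreline_distance(pts, phantom)
    keep <- memb$distance <= phantom$inner_radius + 1e-12
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 1)
    stop("undefined objective: no simulated points inside the phantom")
  d <- min_dist(pts, reference)
  sqrt(mean(d^2))
}

#' Calibration problem definition
#'
#' Bundles the phantom, the reference centreline, the insertion schedule
#' and which material parameters are free (with bounds) for
#' [optimize_parameters()].
#'
#' @param phantom A `tube_phantom`.
#' @param reference A [reference_centreline()].
#' @param drive An [insertion_drive()] that fully inserts the instrument.
#' @param duration Drive duration (s).
#' @param params Baseline [material_params()]; fixed parameters keep
#'   these values.
#' @param free Character vector naming free parameters, a subset of
#'   `young_modulus_shaft`, `radius`, `density`,
#'   `parallel_spring_constant`, `tip_modulus_ratio`.
#' @param lower,upper Named bounds (finite, positive) for the free
#'   parameters; `tip_modulus_ratio` bounds must lie in (0, 1].
#' @param n_points,total_length Rod discretization.
#' @param config A [sim_config()].
#' @param settle_tol Equilibrium speed tolerance (m/s).
#' @param settle_max_steps Settling step cap.
#' @return A `calibration_problem`.
#' @export
calibration_problem <- function(phantom, reference, drive, duration, params,
                                free = c("young_modulus_shaft",
                                         "tip_modulus_ratio"),
                                lower, upper, n_points, total_length,
                                config = sim_config(),
                                settle_tol = 1e-5,
                                settle_max_steps = 4000L) {
  allowed <- c("young_modulus_shaft", "radius", "density",
               "parallel_spring_constant", "tip_modulus_ratio")
  stopifnot(all(free %in% allowed),
            all(free %in% names(lower)), all(free %in% names(upper)))
  lower <- unlist(lower)[free]; upper <- unlist(upper)[free]
  stopifnot(all(is.finite(lower)), all(is.finite(upper)),
            all(lower > 0), all(lower < upper))
  if ("tip_modulus_ratio" %in% free)
    stopifnot(upper[["tip_modulus_ratio"]] <= 1)
  out <- list(phantom = phantom, reference = reference, drive = drive,
              duration = duration, params = params, free = free,
              lower = lower, upper = upper, n_points = n_points,
              total_length = total_length, config = config,
              settle_tol = settle_tol,
              settle_max_steps = as.integer(settle_max_steps))
  class(out) <- "calibration_problem"
  out
}

#' Simulate an insertion to mechanical equilibrium
#'
#' Runs the full pipeline (rod forces, constraint solver, collision)
#' through the problem's insertion schedule, then settles with zero drive
#' until the maximum point speed falls below the tolerance (or the step
#' cap). Deterministic given identical inputs.
#'
#' @param problem A [calibration_problem()].
#' @param params [material_params()] to simulate with.
#' @return Matrix of final in-phantom mass point positions (m), with the
#'   full simulation attached as attribute `"sim"`. On numerical blow-up
#'   returns NULL (objective treated as +Inf).
#' @export
simulate_to_equilibrium <- function(problem, params) {
  rod <- build_rod(problem$n_points, problem$total_length, params,
                   base_position = problem$phantom$centreline$points[1, ],
                   base_axis = c(1, 0, 0), inserted_length = 0)
  rod <- advance_insertion(rod, dt = 0, push_speed = 0)
  sim <- tryCatch(
    simulate_insertion(rod, params, problem$phantom, problem$drive,
                       problem$config, problem$duration,
                       settle_tol = problem$settle_tol,
                       settle_max_steps = problem$settle_max_steps),
    error = function(e) NULL)
  if (is.null(sim)) return(NULL)
  final <- sim$rod
  idx <- which(final$inv_mass > 0 & seq_len(nrow(final$points)) <= final$active_count)
  pts <- final$points[idx, , drop = FALSE]
  memb <- tube_centreline_distance(pts, problem$phantom)
  keep <- memb$distance <= problem$phantom$inner_radius + 1e-12
  structure(pts[keep, , drop = FALSE], sim = sim)
}

calibration_objective <- function(problem, params) {
  pts <- simulate_to_equilibrium(problem, params)
  if (is.null(pts) || nrow(pts) < 1) return(Inf)
  rms_error(pts, problem$reference)
}

#' Calibrate instrument parameters against a reference centreline
#'
#' Minimizes the RMS centreline distance over the free parameters with
#' multi-start Nelder-Mead in a log-transformed box (the parameters span
#' orders of magnitude and are strictly positive). The shear modulus is
#' never varied. Starts are the box centre plus `n_starts - 1`
#' pseudo-random points drawn with the given seed; the search is
#' deterministic given the seed.
#'
#' @param problem A [calibration_problem()].
#' @param n_starts Number of Nelder-Mead starts.
#' @param maxit Iterations per start.
#' @param seed Integer seed for the start draws.
#' @return A `calibration_result`: `best_parameters`
#'   ([material_params()]), `objective_value` (re-evaluated at the
#'   optimum), `evaluation_count` and the per-evaluation `trace`.
#' @export
optimize_parameters <- function(problem, n_starts = 5L, maxit = 60L,
                                seed = 1L) {
  free <- problem$free
  lo <- log(problem$lower); hi <- log(problem$upper)
  env <- new.env()
  env$trace <- list(); env$count <- 0L
  obj <- function(z) {
    if (any(z < lo - 1e-12) || any(z > hi + 1e-12)) {
      over <- sum(pmax(z - hi, 0) + pmax(lo - z, 0))
      return(1 + over) # gentle out-of-bounds penalty (objective is in m)
    }
    p <- problem$params
    p[free] <- as.list(exp(z))
    p$tip_point_count <- as.integer(p$tip_point_count)
    f <- calibration_objective(problem, p)
    env$count <- env$count + 1L
    env$trace[[env$count]] <- list(parameters = setNames(exp(z), free),
                                   objective = f)
    f
  }
  set.seed(seed)
  starts <- rbind((lo + hi) / 2,
                  if (n_starts > 1)
                    matrix(runif((n_starts - 1) * length(free), lo, hi),
                           ncol = length(free), byrow = FALSE))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value))
    stop("calibration failed: all starts diverged (see trace)")
  p <- problem$params
  p[free] <- as.list(exp(best$par))
  p$tip_point_count <- as.integer(p$tip_point_count)
  final_obj <- calibration_objective(problem, p)
  out <- list(best_parameters = p, objective_value = final_obj,
              evaluation_count = env$count, trace = env$trace,
              free = free, seed = seed)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Instrument calibration result\n")
  cat(sprintf("  RMS centreline distance: %.4f mm (%d evaluations)\n",
              1e3 * x$objective_value, x$evaluation_count))
  for (nm in x$free)
    cat(sprintf("  %s = %.4g\n", nm, x$best_parameters[[nm]]))
  invisible(x)
}

#' @export
summary.calibration_result <- function(object, ...) {
  objs <- vapply(object$trace, `[[`, numeric(1), "objective")
  cat("Calibration summary\n")
  cat(sprintf("  evaluations: %d, best %.4f mm, median %.4f mm\n",
              length(objs), 1e3 * min(objs), 1e3 * stats::median(objs[is.finite(objs)])))
  print(object$best_parameters)
  invisible(object)
}
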