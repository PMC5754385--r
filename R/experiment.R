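# The rod-compression benchmark: push a long rod through a bent tube and
# measure how much of its nominal length is lost to compression under
# each distance-constraint strategy.

#' Canonical compression scenario
#'
#' A 255-mm rod of 256 mass points pushed at 20 mm/s into a capped tube
#' phantom (lumen radius 2.5 mm, 90 degree bend of 30 mm bend radius
#' between 100-mm straights) until fully inserted. The tube centreline is
#' shorter than the rod, so continued feeding after the tip reaches the
#' distal dome forces the rod to compress and buckle - the regime where
#' the distance-constraint strategies separate.
#'
#' @param n_points Rod discretization.
#' @param total_length Rod length (m).
#' @param push_speed Insertion speed (m/s).
#' @param params Instrument [material_params()].
#' @param config Base [sim_config()].
#' @return A `compression_scenario` list.
#' @export
canonical_compression_scenario <- function(n_points = 256L,
                                           total_length = 0.255,
                                           push_speed = 0.02,
                                           params = material_params(),
                                           config = sim_config()) {
  phantom <- make_tube_phantom(inner_radius = 2.5e-3, bend_angle = 90,
                               bend_radius = 0.03,
                               straight_lengths = c(0.1, 0.1),
                               capped = TRUE)
  out <- list(phantom = phantom, n_points = as.integer(n_points),
              total_length = total_length, push_speed = push_speed,
              params = params, config = config,
              duration = total_length / push_speed,
              drive = insertion_drive(0, push_speed, 0))
  class(out) <- "compression_scenario"
  out
}

#' Compression over both percentage bases
#'
#' Percent compression of the active rod over (a) the whole active
#' nominal length and (b) the post-bend portion (points whose nearest
#' centreline arc position lies past the bend entrance), plus the
#' absolute compression in mm.
#'
#' @param rod Final `rod_state`.
#' @param phantom The `tube_phantom` it was inserted into.
#' @return List `total_percent`, `postbend_percent`, `compression_mm`.
#' @export
compression_bases <- function(rod, phantom) {
  act <- rod$active_count
  pts <- rod$points[seq_len(act), , drop = FALSE]
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                          pts[-act, , drop = FALSE])^2))
  nominal <- (act - 1) * rod$rest_segment_length
  total_pct <- 100 * (nominal - sum(seglen)) / nominal
  comp_mm <- 1e3 * (nominal - sum(seglen))
  arcpos <- tube_centreline_distance(pts, phantom)$arc
  pb <- which(arcpos >= phantom$arc_bend_start)
  pb <- pb[pb < act]
  if (length(pb) >= 2) {
    nom_pb <- length(pb) * rod$rest_segment_length
    arc_pb <- sum(seglen[pb])
    pb_pct <- 100 * (nom_pb - arc_pb) / nom_pb
  } else pb_pct <- NA_real_
  list(total_percent = total_pct, postbend_percent = pb_pct,
       compression_mm = comp_mm)
}

#' Run the compression benchmark over solver variants
#'
#' Runs the identical insertion schedule from the identical initial state
#' for each (distance mode, iteration count) variant and records the
#' final compression (both percentage bases), the compression in mm, and
#' segment-error diagnostics. The iteration count maps to PGS outer
#' iterations: each outer iteration performs one global tridiagonal solve
#' or one local sweep, followed by the contact phase, re-linearized at
#' predicted positions. Penalty mode uses the largest stable stretch
#' stiffness found by [tune_penalty_stiffness()]. Deterministic given
#' (scenario, seed).
#'
#' @param scenario A [canonical_compression_scenario()].
#' @param variants Data frame with columns `mode` (a
#'   [sim_config()] `distance_mode`) and `iterations`.
#' @param seed Integer recorded in the metadata (the benchmark itself is
#'   deterministic).
#' @param record_stride Trace stride passed to the simulator.
#' @return An `experiment_report`: `results` data frame plus metadata.
#' @export
run_compression_experiment <- function(scenario = canonical_compression_scenario(),
                                       variants = data.frame(
                                         mode = c("penalty",
                                                  rep("global_tridiagonal", 4),
                                                  rep("local_gauss_seidel", 3),
                                                  rep("local_jacobi", 3)),
                                         iterations = c(1, 1, 5, 10, 25,
                                                        1, 10, 100, 1, 10, 100)),
                                       seed = 1L, record_stride = 0L) {
  rod0 <- build_rod(scenario$n_points, scenario$total_length,
                    scenario$params,
                    base_position = scenario$phantom$centreline$points[1, ],
                    base_axis = c(1, 0, 0), inserted_length = 0)
  rod0 <- advance_insertion(rod0, dt = 0, push_speed = 0)
  ks <- NA_real_
  if (any(variants$mode == "penalty"))
    ks <- tune_penalty_stiffness(rod0, scenario$params, scenario$config)
  rows <- vector("list", nrow(variants))
  traces <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    cfg <- scenario$config
    cfg$distance_mode <- as.character(variants$mode[v])
    it <- as.integer(variants$iterations[v])
    if (cfg$distance_mode == "penalty") {
      cfg$penalty_stiffness <- ks
      cfg$outer_iterations <- 1L
    } else {
      cfg$outer_iterations <- it
      cfg$distance_iterations <- 1L
    }
    t0 <- proc.time()[["elapsed"]]
    sim <- tryCatch(
      simulate_insertion(rod0, scenario$params, scenario$phantom,
                         scenario$drive, cfg, scenario$duration,
                         record_stride = record_stride),
      error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(sim, "error")) {
      rows[[v]] <- data.frame(mode = cfg$distance_mode, iterations = it,
                              compression_percent = NA_real_,
                              compression_percent_postbend = NA_real_,
                              compression_mm = NA_real_,
                              max_segment_error_mm = NA_real_,
                              contacts = NA_integer_,
                              wall_seconds = elapsed,
                              status = paste("blow-up:", conditionMessage(sim)))
      next
    }
    cb <- compression_bases(sim$rod, scenario$phantom)
    rows[[v]] <- data.frame(mode = cfg$distance_mode, iterations = it,
                            compression_percent = cb$total_percent,
                            compression_percent_postbend = cb$postbend_percent,
                            compression_mm = cb$compression_mm,
                            max_segment_error_mm = 1e3 * sim$final_max_segment_error,
                            contacts = sim$final_contact_count,
                            wall_seconds = elapsed,
                            status = "ok")
    traces[[v]] <- sim$trace
  }
  out <- list(results = do.call(rbind, rows),
              traces = traces,
              penalty_stiffness = ks,
              seed = as.integer(seed),
              scenario = list(n_points = scenario$n_points,
                              total_length = scenario$total_length,
                              push_speed = scenario$push_speed,
                              duration = scenario$duration,
                              dt = scenario$config$dt))
  class(out) <- "experiment_report"
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Rod compression benchmark\n")
  cat(sprintf("  %d-point rod, %.0f mm, push %.0f mm/s, dt %.0f ms\n",
              x$scenario$n_points, 1e3 * x$scenario$total_length,
              1e3 * x$scenario$push_speed, 1e3 * x$scenario$dt))
  if (is.finite(x$penalty_stiffness))
    cat(sprintf("  penalty stiffness (largest stable): %.3g N/m\n",
                x$penalty_stiffness))
  df <- x$results
  df$compression_percent <- round(df$compression_percent, 2)
  df$compression_percent_postbend <- round(df$compression_percent_postbend, 2)
  df$compression_mm <- round(df$compression_mm, 2)
  print(df[, c("mode", "iterations", "compression_percent",
               "compression_percent_postbend", "compression_mm", "status")],
        row.names = FALSE)
  invisible(x)
}

#' Write an experiment report to CSV + JSON
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$results, file.path(dir, "compression.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(results = report$results, scenario = report$scenario,
         penalty_stiffness = report$penalty_stiffness, seed = report$seed),
    file.path(dir, "compression.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
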