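# Synthetic vascular phantoms: straight-toroidal-straight tubes with known
# analytic centrelines, optionally closed by hemispherical end domes (every
# dome vertex remains exactly one lumen radius from the centreline
# endpoint, so the whole surface is equidistant from the centreline).

# analytic centreline of a straight/arc/straight tube, arc-length param
tube_path <- function(s, L1, Rb, theta, L2) {
  arc <- Rb * theta
  p <- matrix(0, length(s), 3)
  t <- matrix(0, length(s), 3)
  for (i in seq_along(s)) {
    si <- s[i]
    if (si <= L1 || theta == 0) {
      p[i, ] <- c(si, 0, 0); t[i, ] <- c(1, 0, 0)
    } else if (si <= L1 + arc) {
      phi <- (si - L1) / Rb
      p[i, ] <- c(L1 + Rb * sin(phi), Rb * (1 - cos(phi)), 0)
      t[i, ] <- c(cos(phi), sin(phi), 0)
    } else {
      phi <- theta
      pe <- c(L1 + Rb * sin(phi), Rb * (1 - cos(phi)), 0)
      te <- c(cos(phi), sin(phi), 0)
      p[i, ] <- pe + (si - L1 - arc) * te
      t[i, ] <- te
    }
  }
  list(point = p, tangent = t)
}

#' Synthetic bent-tube vascular phantom
#'
#' Generates a watertight tube of constant lumen radius: a straight
#' proximal section, a toroidal bend of given angle and bend radius in the
#' x-y plane, a straight distal section, and (optionally) hemispherical
#' end domes centred on the centreline endpoints. Triangle normals point
#' into the lumen and the exact analytic centreline is returned alongside
#' the mesh. Every surface vertex lies exactly `inner_radius` from the
#' analytic centreline. The construction is deterministic.
#'
#' @param inner_radius Lumen radius (m).
#' @param bend_angle Bend angle in degrees, in \[0, 180\] (0 gives a
#'   straight tube).
#' @param bend_radius Bend (torus centreline) radius (m); must exceed
#'   `inner_radius`.
#' @param straight_lengths Lengths (m) of the proximal and distal straight
#'   sections, `c(L1, L2)`.
#' @param segments Circumferential segment count.
#' @param axial_step Approximate axial ring spacing (m).
#' @param capped Close both ends with hemispherical domes.
#' @param centreline_step Sampling step (m) of the returned centreline
#'   polyline.
#' @param radius_fun Optional radius profile `function(s)` overriding the
#'   constant lumen radius (used by [make_stenosed_vessel()]).
#' @return A `tube_phantom`: list with `mesh` ([triangle_mesh()]),
#'   `centreline` ([reference_centreline()]), `inner_radius`, arc marks
#'   `arc_bend_start`/`arc_bend_end`, `total_arc`, and the generator
#'   parameters.
#' @export
make_tube_phantom <- function(inner_radius, bend_angle, bend_radius,
                              straight_lengths, segments = 24L,
                              axial_step = 1.5e-3, capped = TRUE,
                              centreline_step = 5e-4, radius_fun = NULL) {
  stopifnot(inner_radius > 0, all(straight_lengths > 0), bend_radius > 0)
  if (bend_angle < 0 || bend_angle > 180)
    stop("bend_angle must be in [0, 180] degrees")
  theta <- bend_angle * pi / 180
  if (theta > 0 && bend_radius <= inner_radius)
    stop("self-intersecting tube: bend_radius must exceed inner_radius")
  L1 <- straight_lengths[1]; L2 <- straight_lengths[2]
  total <- L1 + bend_radius * theta + L2
  rad <- if (is.null(radius_fun)) function(s) rep(inner_radius, length(s)) else radius_fun

  n_ax <- max(2L, ceiling(total / axial_step) + 1L)
  svals <- seq(0, total, length.out = n_ax)
  path <- tube_path(svals, L1, bend_radius, theta, L2)
  ns <- as.integer(segments)
  psi <- 2 * pi * (seq_len(ns) - 1) / ns

  verts <- list(); faces <- list(); anchors <- list()
  ring_id <- matrix(0L, n_ax, ns)
  vcount <- 0L
  ring_vertex <- function(P, t, r, psi) {
    n1 <- c(0, 0, 1)
    n2 <- c(t[2], -t[1], 0)  # t x z for planar tangents
    n2 <- n2 / sqrt(sum(n2^2))
    P + r * (cos(psi) * n2 + sin(psi) * n1)
  }
  for (k in seq_len(n_ax)) {
    r_k <- rad(svals[k])[1]
    ring <- t(vapply(psi, function(a)
      ring_vertex(path$point[k, ], path$tangent[k, ], r_k, a), numeric(3)))
    verts[[k]] <- ring
    ring_id[k, ] <- vcount + seq_len(ns)
    vcount <- vcount + ns
  }
  add_face <- function(i, j, k, anchor) {
    faces[[length(faces) + 1L]] <<- c(i, j, k)
    anchors[[length(anchors) + 1L]] <<- anchor
  }
  for (k in seq_len(n_ax - 1L)) {
    anchor <- (path$point[k, ] + path$point[k + 1L, ]) / 2
    for (i in seq_len(ns)) {
      i2 <- if (i == ns) 1L else i + 1L
      a <- ring_id[k, i]; b <- ring_id[k, i2]
      c_ <- ring_id[k + 1L, i2]; d <- ring_id[k + 1L, i]
      add_face(a, b, c_, anchor)
      add_face(a, c_, d, anchor)
    }
  }
  if (capped) {
    for (end in c(1L, 2L)) {
      if (end == 1L) {
        P <- path$point[1, ]; out <- -path$tangent[1, ]
        base <- ring_id[1, ]; r_e <- rad(0)[1]
      } else {
        P <- path$point[n_ax, ]; out <- path$tangent[n_ax, ]
        base <- ring_id[n_ax, ]; r_e <- rad(total)[1]
      }
      nring <- 3L
      chi <- (seq_len(nring) / (nring + 1L)) * (pi / 2)
      prev <- base
      for (cc in chi) {
        ring <- t(vapply(psi, function(a) {
          n1 <- c(0, 0, 1)
          tt <- if (end == 1L) path$tangent[1, ] else path$tangent[n_ax, ]
          n2 <- c(tt[2], -tt[1], 0); n2 <- n2 / sqrt(sum(n2^2))
          P + r_e * (cos(cc) * (cos(a) * n2 + sin(a) * n1) + sin(cc) * out)
        }, numeric(3)))
        verts[[length(verts) + 1L]] <- ring
        ids <- vcount + seq_len(ns); vcount <- vcount + ns
        for (i in seq_len(ns)) {
          i2 <- if (i == ns) 1L else i + 1L
          add_face(prev[i], prev[i2], ids[i2], P)
          add_face(prev[i], ids[i2], ids[i], P)
        }
        prev <- ids
      }
      verts[[length(verts) + 1L]] <- matrix(P + r_e * out, 1, 3)
      pole <- vcount + 1L; vcount <- vcount + 1L
      for (i in seq_len(ns)) {
        i2 <- if (i == ns) 1L else i + 1L
        add_face(prev[i], prev[i2], pole, P)
      }
    }
  }
  V <- do.call(rbind, verts)
  F_ <- do.call(rbind, faces)
  A <- do.call(rbind, anchors)
  # orient normals into the lumen (towards the local centreline anchor)
  N <- face_normals(V, F_)
  centroid <- (V[F_[, 1], , drop = FALSE] + V[F_[, 2], , drop = FALSE] +
               V[F_[, 3], , drop = FALSE]) / 3
  flip <- rowSums(N * (A - centroid)) < 0
  F_[flip, c(2, 3)] <- F_[flip, c(3, 2)]
  mesh <- triangle_mesh(V, F_)

  ncl <- max(2L, ceiling(total / centreline_step) + 1L)
  scl <- seq(0, total, length.out = ncl)
  cl <- reference_centreline(tube_path(scl, L1, bend_radius, theta, L2)$point)
  out <- list(mesh = mesh, centreline = cl, inner_radius = inner_radius,
              arc_bend_start = L1, arc_bend_end = L1 + bend_radius * theta,
              total_arc = total, bend_angle = bend_angle,
              bend_radius = bend_radius, straight_lengths = straight_lengths,
              capped = capped, segments = ns)
  class(out) <- "tube_phantom"
  out
}

#' @export
print.tube_phantom <- function(x, ...) {
  cat(sprintf(
    "Tube phantom: radius %.2f mm, %g deg bend (R = %.0f mm), arc %.1f mm, %d triangles%s\n",
    1e3 * x$inner_radius, x$bend_angle, 1e3 * x$bend_radius,
    1e3 * x$total_arc, nrow(x$mesh$faces), if (x$capped) ", capped" else ""))
  invisible(x)
}

#' Exact distance from points to the analytic tube centreline
#'
#' Closed-form distance to the straight-arc-straight curve of a
#' [make_tube_phantom()] (not its sampled polyline), used for construction
#' audits and lumen membership tests.
#'
#' @param points n x 3 matrix (m).
#' @param phantom A `tube_phantom`.
#' @return List with `distance` (m) and `arc` (nearest arc position, m).
#' @export
tube_centreline_distance <- function(points, phantom) {
  L1 <- phantom$straight_lengths[1]; L2 <- phantom$straight_lengths[2]
  Rb <- phantom$bend_radius; theta <- phantom$bend_angle * pi / 180
  arcL <- Rb * theta
  total <- phantom$total_arc
  pts <- as.matrix(points)
  n <- nrow(pts)
  d <- numeric(n); arc <- numeric(n)
  e2 <- tube_path(total, L1, Rb, theta, L2)
  p_end <- e2$point[1, ]; t_end <- e2$tangent[1, ]
  for (i in seq_len(n)) {
    p <- pts[i, ]
    cand_d <- numeric(0); cand_s <- numeric(0)
    # proximal straight: clamp x to [0, L1]
    s1 <- min(max(p[1], 0), L1)
    cand_d <- c(cand_d, sqrt(sum((p - c(s1, 0, 0))^2))); cand_s <- c(cand_s, s1)
    if (theta > 0) {
      # arc: circle of radius Rb centred at (L1, Rb, 0) in z = 0 plane
      v <- c(p[1] - L1, p[2] - Rb)
      phi <- atan2(v[1], -v[2]) # angle from arc start
      phi <- min(max(phi, 0), theta)
      q <- c(L1 + Rb * sin(phi), Rb * (1 - cos(phi)), 0)
      cand_d <- c(cand_d, sqrt(sum((p - q)^2)))
      cand_s <- c(cand_s, L1 + Rb * phi)
    }
    # distal straight
    u <- sum((p - p_end) * t_end)
    u <- min(max(u, -L2), 0)
    q <- p_end + u * t_end
    cand_d <- c(cand_d, sqrt(sum((p - q)^2))); cand_s <- c(cand_s, total + u)
    j <- which.min(cand_d)
    d[i] <- cand_d[j]; arc[i] <- cand_s[j]
  }
  list(distance = d, arc = arc)
}

#' Stenosed / healthy vessel mesh pair
#'
#' The healthy vessel is a plain tube; the stenosed one narrows the lumen
#' radius by a smooth cosine-squared bump of the given severity centred at
#' `stenosis_center` (arc length) over `extent`. Both meshes share the
#' same topology, so they can be linearly morphed into each other during
#' balloon inflation.
#'
#' @param inner_radius,bend_angle,bend_radius,straight_lengths,segments,axial_step,capped
#'   Base tube parameters, as in [make_tube_phantom()].
#' @param stenosis_center Arc-length position of the stenosis throat (m).
#' @param severity Fractional radius reduction at the throat, in (0, 1).
#' @param extent Axial extent of the stenosis (m).
#' @return List with `stenosed` and `healthy` (`tube_phantom` objects).
#' @export
make_stenosed_vessel <- function(inner_radius, bend_angle = 0,
                                 bend_radius = 0.03,
                                 straight_lengths = c(0.03, 0.03),
                                 stenosis_center, severity, extent,
                                 segments = 24L, axial_step = 1.5e-3,
                                 capped = FALSE) {
  if (severity <= 0 || severity >= 1) stop("severity must be in (0, 1)")
  theta <- bend_angle * pi / 180
  total <- straight_lengths[1] + bend_radius * theta + straight_lengths[2]
  if (extent > total) stop("stenosis extent exceeds tube length")
  window <- function(s) {
    w <- numeric(length(s))
    inb <- abs(s - stenosis_center) < extent / 2
    w[inb] <- 0.5 * (1 + cos(2 * pi * (s[inb] - stenosis_center) / extent))
    w
  }
  healthy <- make_tube_phantom(inner_radius, bend_angle, bend_radius,
                               straight_lengths, segments, axial_step, capped)
  stenosed <- make_tube_phantom(inner_radius, bend_angle, bend_radius,
                                straight_lengths, segments, axial_step, capped,
                                radius_fun = function(s)
                                  inner_radius * (1 - severity * window(s)))
  list(stenosed = stenosed, healthy = healthy)
}
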