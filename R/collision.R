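#' Triangle mesh container
#'
#' @param vertices n x 3 numeric matrix of vertex positions (m).
#' @param faces k x 3 integer matrix of 1-based vertex indices. Triangles
#'   are wound so their normals point into the lumen.
#' @return A `triangle_mesh` with per-triangle unit `normals`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(faces) < 1) stop("empty mesh")
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  m <- list(vertices = vertices, faces = faces,
            normals = face_normals(vertices, faces))
  class(m) <- "triangle_mesh"
  m
}

face_normals <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.eps)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Build a fat-AABB bounding volume hierarchy over a mesh
#'
#' Binary tree by longest-axis median split over triangle centroids. The
#' topology is fixed at build time; only box positions and extents are
#' recomputed on [refit_aabb_tree()], so the same tree can follow a
#' deforming (e.g. beating-heart) mesh. Leaf boxes are enlarged by
#' `fat_margin` so small per-step motion cannot escape them.
#'
#' @param mesh A [triangle_mesh()].
#' @param fat_margin Fat margin (m); a good default is twice the
#'   instrument radius.
#' @return An `aabb_tree` handle.
#' @export
build_aabb_tree <- function(mesh, fat_margin) {
  ptr <- cpp_build_tree(mesh$vertices, mesh$faces, fat_margin)
  out <- list(ptr = ptr, n_triangles = nrow(mesh$faces),
              n_vertices = nrow(mesh$vertices), fat_margin = fat_margin)
  class(out) <- "aabb_tree"
  out
}

#' Refit the tree boxes to moved vertices
#'
#' Bottom-up box update over the unchanged topology; each node is touched
#' exactly once regardless of how far the mesh moved.
#'
#' @param tree An [build_aabb_tree()] handle.
#' @param mesh The same-topology mesh with updated vertex positions.
#' @return The tree (invisibly); `tree_structure()` exposes the audit
#'   counter of nodes touched.
#' @export
refit_aabb_tree <- function(tree, mesh) {
  if (nrow(mesh$faces) != tree$n_triangles ||
      nrow(mesh$vertices) != tree$n_vertices)
    stop("refit requires identical mesh topology")
  cpp_refit_tree(tree$ptr, mesh$vertices)
  invisible(tree)
}

#' Broad-phase query: triangles near a sphere
#'
#' Returns a superset of all triangles within `radius` of `center`
#' (sphere-vs-AABB descent).
#'
#' @param tree An `aabb_tree`.
#' @param center Sphere centre (length-3, m).
#' @param radius Sphere radius (m), > 0.
#' @return Integer vector of candidate triangle indices (1-based).
#' @export
query_candidates <- function(tree, center, radius) {
  stopifnot(radius > 0)
  sort(cpp_query_tree(tree$ptr, as.numeric(center), radius))
}

#' Internal structure of an AABB tree (for audits)
#'
#' @param tree An `aabb_tree`.
#' @return List of node boxes (`lo`, `hi`), child indices (1-based, 0 for
#'   leaf), leaf triangle ranges, the triangle permutation, the fat margin
#'   and the node count of the last refit.
#' @export
tree_structure <- function(tree) {
  cpp_tree_info(tree$ptr)
}

#' Narrow-phase sphere-vs-triangle contacts of rod points
#'
#' For every dynamic mass point, candidate triangles from the broad phase
#' are tested exactly (closest point on triangle); triangles closer than
#' the instrument radius contribute their oriented normals weighted by
#' penetration depth. The aggregated normal is renormalized (falling back
#' to the deepest triangle's normal when opposing walls cancel) and one
#' contact per colliding point is emitted.
#'
#' @param rod A `rod_state` (only active, dynamic points are tested), or a
#'   plain n x 3 matrix of sphere centres.
#' @param tree An `aabb_tree` refitted to the current mesh.
#' @param params [material_params()] supplying the instrument radius and
#'   friction coefficient.
#' @return A contact set: `point_index`, `normal` (unit rows),
#'   `penetration_depth` (>= 0) and `friction_coefficient`.
#' @export
narrow_phase_contacts <- function(rod, tree, params) {
  if (inherits(rod, "rod_state")) {
    idx <- which(rod$inv_mass > 0 & seq_len(nrow(rod$points)) <= rod$active_count)
    pts <- rod$points[idx, , drop = FALSE]
  } else {
    idx <- seq_len(nrow(rod))
    pts <- as.matrix(rod)
  }
  out <- cpp_narrow_contacts(pts, params$radius, params$friction_coefficient,
                             tree$ptr)
  out$point_index <- idx[out$point_index]
  out
}

#' Resolve contacts by projected impulses with Coulomb friction
#'
#' Gauss-Seidel sweeps over the contact set: each contact receives a
#' non-negative accumulated normal impulse removing approaching normal
#' velocity (plus a Baumgarte share of the penetration depth) and a
#' tangential friction impulse clamped to the Coulomb cone
#' |j_t| <= mu j_n.
#'
#' @param rod A `rod_state` (velocities already include forces).
#' @param contacts A contact set from [narrow_phase_contacts()].
#' @param dt Time step (s).
#' @param stabilization Baumgarte factor.
#' @param iterations Gauss-Seidel sweeps.
#' @return List with the corrected `rod`, `normal_impulse` (>= 0) and
#'   `tangential_impulse` magnitudes per contact.
#' @export
resolve_contacts <- function(rod, contacts, dt = 1e-3, stabilization = 0.2,
                             iterations = 10L) {
  out <- cpp_resolve_contacts(rod, contacts$point_index, contacts$normal,
                              contacts$penetration_depth,
                              contacts$friction_coefficient,
                              dt, stabilization, as.integer(iterations))
  class(out$rod) <- "rod_state"
  out
}

#' Distance from points to a mesh surface
#'
#' Exact minimum point-to-triangle distance over all triangles (no
#' hierarchy; used for balloon fitting and audits).
#'
#' @param points n x 3 matrix (m).
#' @param mesh A [triangle_mesh()].
#' @return Numeric vector of distances (m).
#' @export
point_mesh_distance <- function(points, mesh) {
  cpp_point_mesh_distance(as.matrix(points), mesh$vertices, mesh$faces)
}
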