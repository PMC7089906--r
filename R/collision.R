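#' Moller-Trumbore ray-triangle intersection
#'
#' Tests the unbounded ray `origin + t * direction` (t >= 0) against a
#' single triangle.  The determinant test treats near-parallel rays
#' (|det| below 1e-12 relative to the edge/direction scale) as misses.
#'
#' @param origin,direction length-3 numeric; `direction` must be non-zero.
#' @param v0,v1,v2 triangle vertices (length-3 numeric).
#' @return `NULL` on a miss, otherwise `list(t, u, v)` with `t >= 0` the ray
#'   parameter and `(u, v)` the barycentric coordinates (u, v >= 0,
#'   u + v <= 1).
#' @export
ray_triangle <- function(origin, direction, v0, v1, v2) {
  d <- as.numeric(direction)
  if (sqrt(sum(d^2)) < 1e-300) stop("ray direction must be non-zero")
  e1 <- as.numeric(v1) - as.numeric(v0)
  e2 <- as.numeric(v2) - as.numeric(v0)
  h <- .cross3(d, e2)
  det <- sum(e1 * h)
  scale <- sqrt(sum(e1^2)) * sqrt(sum(h^2))
  if (abs(det) <= 1e-12 * max(scale, 1e-300)) return(NULL)
  f <- 1 / det
  s <- as.numeric(origin) - as.numeric(v0)
  u <- f * sum(s * h)
  if (u < 0 || u > 1) return(NULL)
  q <- .cross3(s, e1)
  v <- f * sum(d * q)
  if (v < 0 || u + v > 1) return(NULL)
  t <- f * sum(e2 * q)
  if (t < 0) return(NULL)
  list(t = t, u = u, v = v)
}

# Vectorised segment-triangle MT over paired rows (exhaustive R path).
# p0, p1: k x 3 segment endpoints; a, b, c: k x 3 triangle vertices.
# Returns list(hit, px, py, pz).  Mirrors src/collision.cpp bit for bit in
# formula order so the broad-phase contract can be checked exactly.
.seg_tri_rows <- function(p0, p1, a, b, c) {
  d <- p1 - p0
  e1 <- b - a
  e2 <- c - a
  hx <- d[, 2] * e2[, 3] - d[, 3] * e2[, 2]
  hy <- d[, 3] * e2[, 1] - d[, 1] * e2[, 3]
  hz <- d[, 1] * e2[, 2] - d[, 2] * e2[, 1]
  det <- e1[, 1] * hx + e1[, 2] * hy + e1[, 3] * hz
  scale <- sqrt(rowSums(e1^2)) * sqrt(hx^2 + hy^2 + hz^2)
  ok <- abs(det) > 1e-12 * pmax(scale, 1e-300)
  f <- ifelse(ok, 1 / det, 0)
  s <- p0 - a
  u <- f * (s[, 1] * hx + s[, 2] * hy + s[, 3] * hz)
  ok <- ok & u >= 0 & u <= 1
  qx <- s[, 2] * e1[, 3] - s[, 3] * e1[, 2]
  qy <- s[, 3] * e1[, 1] - s[, 1] * e1[, 3]
  qz <- s[, 1] * e1[, 2] - s[, 2] * e1[, 1]
  v <- f * (d[, 1] * qx + d[, 2] * qy + d[, 3] * qz)
  ok <- ok & v >= 0 & (u + v) <= 1
  t <- f * (e2[, 1] * qx + e2[, 2] * qy + e2[, 3] * qz)
  ok <- ok & t >= 0 & t <= 1
  list(hit = ok, p = p0 + d * t)
}

# all segments (P0 -> P1) vs all triangles of (V, F), pure R, chunked
.edges_vs_mesh_exhaustive <- function(P0, P1, V, F, any_hit = FALSE) {
  ne <- nrow(P0)
  m <- nrow(F)
  hit_e <- integer(0); hit_f <- integer(0)
  pts <- matrix(numeric(0), 0L, 3L)
  if (ne == 0L || m == 0L)
    return(list(edge = hit_e, tri = hit_f, points = pts))
  va <- V[F[, 1], , drop = FALSE]
  vb <- V[F[, 2], , drop = FALSE]
  vc <- V[F[, 3], , drop = FALSE]
  chunk <- max(1L, floor(2e6 / m))
  for (start in seq(1L, ne, by = chunk)) {
    eidx <- start:min(ne, start + chunk - 1L)
    k <- length(eidx)
    ee <- rep(eidx, each = m)
    ff <- rep.int(seq_len(m), k)
    res <- .seg_tri_rows(P0[ee, , drop = FALSE], P1[ee, , drop = FALSE],
                         va[ff, , drop = FALSE], vb[ff, , drop = FALSE],
                         vc[ff, , drop = FALSE])
    w <- which(res$hit)
    if (length(w)) {
      hit_e <- c(hit_e, ee[w])
      hit_f <- c(hit_f, ff[w])
      pts <- rbind(pts, res$p[w, , drop = FALSE])
      if (any_hit) break
    }
  }
  list(edge = hit_e, tri = hit_f, points = pts)
}

#' Mesh-mesh surface intersection
#'
#' Treats every edge of mesh A (after `transform_a`) as a segment and tests
#' it against the triangles of mesh B, and symmetrically every edge of B
#' against the triangles of posed A.  Each segment-triangle crossing
#' contributes one boundary point.  This is a surface-crossing test: a mesh
#' entirely inside another without its surface crossing reports no
#' intersection.
#'
#' @param mesh_a,mesh_b [trimesh]es.
#' @param transform_a optional `rigid_transform` applied to mesh A.
#' @param method `"grid"` (uniform-grid broad phase, compiled) or
#'   `"exhaustive"` (all-pairs, pure R).  Both give identical results; the
#'   exhaustive path exists as the reference the accelerated path is tested
#'   against.
#' @param any_hit if TRUE, stop at the first crossing (only `intersects` is
#'   then meaningful).
#' @return An object of class `mesh_intersection`: `intersects` (logical),
#'   `boundary_points` (k x 3, deduplicated at 1e-9 mm), `crossed_faces_a`,
#'   `crossed_faces_b` (face ids whose plane carries a boundary point:
#'   faces incident to a crossed edge, plus faces pierced by an opposing
#'   edge), and `crossed_vertices_a`, `crossed_vertices_b` (vertices
#'   incident to the crossing).
#' @export
mesh_intersect <- function(mesh_a, mesh_b, transform_a = NULL,
                           method = c("grid", "exhaustive"),
                           any_hit = FALSE) {
  stopifnot(inherits(mesh_a, "trimesh"), inherits(mesh_b, "trimesh"))
  method <- match.arg(method)
  va <- mesh_a$vertices
  if (!is.null(transform_a)) va <- tf_apply(transform_a, va)
  vb <- mesh_b$vertices
  ea <- mesh_a$edges
  eb <- mesh_b$edges
  fa0 <- mesh_a$faces - 1L
  fb0 <- mesh_b$faces - 1L
  run <- function(P0, P1, V, F0) {
    if (method == "grid")
      edges_vs_mesh_cpp(P0, P1, V, F0, any_hit, TRUE)
    else
      .edges_vs_mesh_exhaustive(P0, P1, V, F0 + 1L, any_hit)
  }
  r_ab <- run(va[ea[, 1], , drop = FALSE], va[ea[, 2], , drop = FALSE],
              vb, fb0)
  hit <- length(r_ab$edge) > 0L
  if (any_hit && hit) {
    return(structure(list(intersects = TRUE,
                          boundary_points = matrix(numeric(0), 0, 3),
                          crossed_faces_a = integer(0),
                          crossed_faces_b = integer(0),
                          crossed_vertices_a = integer(0),
                          crossed_vertices_b = integer(0)),
                     class = "mesh_intersection"))
  }
  r_ba <- run(vb[eb[, 1], , drop = FALSE], vb[eb[, 2], , drop = FALSE],
              va, fa0)
  hit <- hit || length(r_ba$edge) > 0L
  if (any_hit) {
    return(structure(list(intersects = hit,
                          boundary_points = matrix(numeric(0), 0, 3),
                          crossed_faces_a = integer(0),
                          crossed_faces_b = integer(0),
                          crossed_vertices_a = integer(0),
                          crossed_vertices_b = integer(0)),
                     class = "mesh_intersection"))
  }
  # crossed edges and incident entities
  cf_a <- sort(unique(c(as.vector(mesh_a$edge_faces[r_ab$edge, ]),
                        r_ba$tri)))
  cf_a <- cf_a[!is.na(cf_a)]
  cf_b <- sort(unique(c(as.vector(mesh_b$edge_faces[r_ba$edge, ]),
                        r_ab$tri)))
  cf_b <- cf_b[!is.na(cf_b)]
  cv_a <- sort(unique(c(as.vector(ea[r_ab$edge, , drop = FALSE]),
                        as.vector(mesh_a$faces[r_ba$tri, , drop = FALSE]))))
  cv_b <- sort(unique(c(as.vector(eb[r_ba$edge, , drop = FALSE]),
                        as.vector(mesh_b$faces[r_ab$tri, , drop = FALSE]))))
  pts <- rbind(r_ab$points, r_ba$points)
  if (nrow(pts) > 1L) {
    key <- paste(round(pts[, 1] / 1e-9), round(pts[, 2] / 1e-9),
                 round(pts[, 3] / 1e-9))
    pts <- pts[!duplicated(key), , drop = FALSE]
  }
  structure(list(intersects = nrow(pts) > 0L,
                 boundary_points = pts,
                 crossed_faces_a = as.integer(cf_a),
                 crossed_faces_b = as.integer(cf_b),
                 crossed_vertices_a = as.integer(cv_a),
                 crossed_vertices_b = as.integer(cv_b)),
            class = "mesh_intersection")
}

#' @export
print.mesh_intersection <- function(x, ...) {
  cat("mesh_intersection:",
      if (x$intersects) "surfaces cross" else "no crossing", "\n")
  cat("  boundary points:", nrow(x$boundary_points),
      "| crossed faces A:", length(x$crossed_faces_a),
      "B:", length(x$crossed_faces_b), "\n")
  invisible(x)
}

#' Prosthetic impingement check
#'
#' TRUE iff the stem/neck surface crosses the liner surface at the given
#' pose.  An empty liner mesh never impinges.
#'
#' @param stem,liner [trimesh]es.
#' @param transform `rigid_transform` posing the stem.
#' @export
check_pi <- function(stem, liner, transform = NULL) {
  if (nrow(liner$faces) == 0L || nrow(stem$faces) == 0L) return(FALSE)
  mesh_intersect(stem, liner, transform_a = transform,
                 any_hit = TRUE)$intersects
}

#' Point-in-mesh test by ray parity
#'
#' Casts a ray from `point` and counts surface crossings; an odd count
#' means inside.  Requires a closed mesh.  Directions grazing an edge or
#' vertex are detected (barycentric coordinate within 1e-9 of the border)
#' and retried along a different direction.
#'
#' @param point length-3 numeric.
#' @param mesh a closed [trimesh].
#' @param transform optional `rigid_transform` applied to the mesh.
#' @export
point_in_mesh <- function(point, mesh, transform = NULL) {
  v <- mesh$vertices
  if (!is.null(transform)) v <- tf_apply(transform, v)
  dirs <- list(c(0.57735026, 0.57735027, 0.57735028),
               c(-0.27216553, 0.68041382, 0.68041381),
               c(0.80178373, -0.26726124, 0.53452248),
               c(0.11043153, 0.33129459, 0.93700399))
  for (d in dirs) {
    hits <- ray_mesh_hits_cpp(as.numeric(point), d, v, mesh$faces - 1L)
    if (nrow(hits) == 0L) return(FALSE)
    degen <- hits[, "u"] < 1e-9 | hits[, "v"] < 1e-9 |
      hits[, "u"] + hits[, "v"] > 1 - 1e-9 | hits[, "t"] < 1e-12
    if (!any(degen)) return(nrow(hits) %% 2L == 1L)
  }
  # all directions grazed; fall back to the last parity
  nrow(hits) %% 2L == 1L
}
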