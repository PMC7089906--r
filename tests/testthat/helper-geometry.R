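# Shared geometric helpers and independent oracles for the test suite.

sphere_mesh <- function(radius, center = c(0, 0, 0), edge) {
  impingemap:::.as_trimesh(impingemap:::.mesh_sphere(radius, center, edge))
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

rand_rotation <- function(center = c(0, 0, 0)) {
  tf_rotation(rand_unit(), stats::runif(1, 0, 360), center)
}

# Independent ray-triangle oracle: plane intersection followed by
# barycentric coordinates from dot products (no Moller-Trumbore terms).
plane_bary_hit <- function(origin, dir, v0, v1, v2) {
  e1 <- v1 - v0
  e2 <- v2 - v0
  n <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  denom <- sum(n * dir)
  if (abs(denom) <= 1e-12 * sqrt(sum(n^2)) * sqrt(sum(dir^2))) return(NULL)
  t <- sum(n * (v0 - origin)) / denom
  if (t < 0) return(NULL)
  p <- origin + t * dir - v0
  d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
  dp1 <- sum(p * e1); dp2 <- sum(p * e2)
  den <- d11 * d22 - d12 * d12
  u <- (d22 * dp1 - d12 * dp2) / den
  v <- (d11 * dp2 - d12 * dp1) / den
  if (u < 0 || v < 0 || u + v > 1) return(NULL)
  list(t = t, u = u, v = v)
}

# Exact point-to-triangle distance (Ericson's region walk).
point_tri_dist <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  den <- 1 / (va + vb + vc)
  v <- vb * den; w <- vc * den
  sqrt(sum((p - (a + v * ab + w * ac))^2))
}

min_dist_to_faces <- function(p, mesh, faces, vertices = mesh$vertices) {
  min(vapply(faces, function(f) {
    tri <- vertices[mesh$faces[f, ], , drop = FALSE]
    point_tri_dist(p, tri[1, ], tri[2, ], tri[3, ])
  }, numeric(1)))
}

# Independent region-growing oracle: breadth-first connected components
# (igraph) over the seed-triangle shared-edge graph.
rga_oracle <- function(mesh, crossed_vertices) {
  vflag <- logical(nrow(mesh$vertices))
  vflag[crossed_vertices] <- TRUE
  seed <- which(!(vflag[mesh$faces[, 1]] | vflag[mesh$faces[, 2]] |
                    vflag[mesh$faces[, 3]]))
  if (length(seed) == 0L) return(list())
  ef <- mesh$edge_faces
  keep <- !is.na(ef[, 2]) & ef[, 1] %in% seed & ef[, 2] %in% seed
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ef[keep, 1]),
               to = as.character(ef[keep, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(seed)))
  comp <- igraph::components(g)
  out <- split(as.integer(igraph::V(g)$name), comp$membership)
  unname(lapply(out, sort))
}

# Random ray/triangle pair with a healthy mix of hits and misses: the ray
# is aimed at a jittered point near the triangle centroid.
rand_ray_triangle <- function() {
  tri <- matrix(stats::rnorm(9, sd = 2), 3)
  o <- stats::rnorm(3, sd = 4)
  target <- colMeans(tri) + stats::rnorm(3, sd = 1.2)
  d <- target - o
  list(tri = tri, o = o, d = d / sqrt(sum(d^2)))
}

clusters_as_sets <- function(cl) {
  sets <- lapply(cl, sort)
  sets[order(vapply(sets, min, numeric(1)))]
}

# Fixture whose pelvis bump is first reached by the femur shaft at a chosen
# tilt (degrees) from the neutral axis, toward conical azimuth 0 (+x).
bump_spec_for_reach <- function(reach_deg, edge = 2.5, ...) {
  rs <- 9; rb <- 5
  D <- 55  # bump centre distance; plate sits at 60 with a 10 mm protrusion
  gamma <- reach_deg + asin((rs + rb) / D) * 180 / pi
  u <- c(sin(gamma * pi / 180), 0, -cos(gamma * pi / 180))
  fixture_spec(mesh_edge_length = edge, shaft_radius = rs, shaft_end = 57,
               plate_distance = 60,
               bump = list(direction = u, height = 10, radius = rb), ...)
}

# Derived angular bound (degrees) on the mesh-discretisation error of the
# rim-contact fixture: the rim ring is a polygon whose chord midpoints sit
# radially inward of the true rim circle, and the neck facets inscribe the
# true cylinder.  Both closed-form perturbed contact angles are compared to
# the smooth-surface angle; 0.2 deg covers second-order cross terms.
rim_mesh_term_deg <- function(spec) {
  Rc <- spec$cup_radius; rn <- spec$neck_radius
  beta <- spec$rim_opening_half_angle
  e <- spec$mesh_edge_length
  tstar <- beta - asin(rn / Rc) * 180 / pi
  nphi_rim <- max(16, ceiling(2 * pi * (Rc + spec$liner_thickness) / e))
  dphi <- pi / nphi_rim
  rho <- Rc * sin(beta * pi / 180)
  zr <- Rc * cos(beta * pi / 180)
  gam <- atan2(rho * cos(dphi), zr) * 180 / pi
  Dp <- sqrt((rho * cos(dphi))^2 + zr^2)
  t_poly <- gam - asin(rn / Dp) * 180 / pi
  nphi_neck <- max(12, ceiling(2 * pi * rn / e))
  t_facet <- beta - asin(rn * cos(pi / nphi_neck) / Rc) * 180 / pi
  abs(t_poly - tstar) + abs(t_facet - tstar) + 0.2
}

# Dense brute-force pose sweep: first tilt (toward azimuth 0) at which two
# meshes of a model cross, by direct rotation and mesh_intersect.
brute_first_crossing_tilt <- function(mesh_a, mesh_b, tilts_deg,
                                      method = "grid") {
  for (t in tilts_deg) {
    tf <- tf_rotation(c(0, 1, 0), -t, c(0, 0, 0))  # -z axis tilts toward +x
    if (mesh_intersect(mesh_a, mesh_b, transform_a = tf, method = method,
                       any_hit = TRUE)$intersects)
      return(t)
  }
  Inf
}
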