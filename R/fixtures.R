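## Parametric hip fixtures with closed-form contact angles.
##
## Frame: hip centre at the origin, neutral femoral axis along -z, cup
## opening about -z.  All closed-form angles below are derived for this
## geometry and cross-checked against brute-force pose sweeps in the tests
## before being used as oracles.

#' Specification of a parametric hip fixture
#'
#' The fixture emulates a planned-implant input set: a spherical-cap liner
#' with a circular rim (inner articulating radius `cup_radius`, opening
#' half-angle `rim_opening_half_angle` about the -z cup axis), a stem made
#' of a ball (`head_radius`) plus a cylindrical neck (`neck_radius`,
#' `neck_length`) on the cup axis, a femur proxy (cylindrical shaft of
#' radius `shaft_radius` spanning axial depths `shaft_start` to
#' `shaft_end`), and a pelvis proxy (flat plate facing the hip centre at
#' distance `plate_distance`, optionally with a spherical prominence bump).
#' All components are concentric and PI-free at the neutral posture.
#'
#' A bump is `list(direction, height, radius)`: a sphere of that radius
#' whose front protrudes `height` mm from the plate's inner face along the
#' unit `direction` from the hip centre (so its centre sits at distance
#' `plate_distance - height + radius`).
#'
#' @param cup_radius liner inner (articulating) radius, mm.
#' @param rim_opening_half_angle cup opening half-angle, deg, in (0, 90).
#' @param head_radius,neck_radius,neck_length stem ball and neck, mm
#'   (`neck_radius < head_radius < cup_radius`).
#' @param liner_thickness shell thickness, mm.
#' @param shaft_radius,shaft_start,shaft_end femur-proxy cylinder, mm.
#' @param plate_distance distance of the pelvis plate inner face, mm; must
#'   exceed the shaft's swept reach.
#' @param plate_half_width,plate_thickness pelvis plate half-extent and
#'   thickness, mm.
#' @param bump optional prominence, see above.
#' @param mesh_edge_length target triangle edge length, mm.
#' @param random_seed recorded for provenance; the mesher itself is fully
#'   deterministic.
#' @export
fixture_spec <- function(cup_radius = 18, rim_opening_half_angle = 55,
                         head_radius = 16, neck_radius = 6,
                         neck_length = 40, liner_thickness = 2,
                         shaft_radius = 9, shaft_start = 20,
                         shaft_end = 57, plate_distance = 60,
                         plate_half_width = 25, plate_thickness = 4,
                         bump = NULL, mesh_edge_length = 1,
                         random_seed = 1L) {
  if (!(neck_radius < head_radius && head_radius < cup_radius))
    stop("need neck_radius < head_radius < cup_radius")
  if (rim_opening_half_angle <= 0 || rim_opening_half_angle >= 90)
    stop("rim_opening_half_angle must be in (0, 90) degrees")
  if (mesh_edge_length <= 0) stop("mesh_edge_length must be > 0")
  if (shaft_start >= shaft_end) stop("need shaft_start < shaft_end")
  reach <- sqrt(shaft_end^2 + shaft_radius^2)
  if (plate_distance <= reach)
    stop(sprintf(
      "plate_distance (%.1f) must exceed the shaft swept reach (%.1f)",
      plate_distance, reach))
  if (!is.null(bump)) {
    stopifnot(is.list(bump),
              all(c("direction", "height", "radius") %in% names(bump)))
    if (bump$height <= 0 || bump$radius <= 0)
      stop("bump height and radius must be > 0")
  }
  structure(list(cup_radius = cup_radius,
                 rim_opening_half_angle = rim_opening_half_angle,
                 head_radius = head_radius, neck_radius = neck_radius,
                 neck_length = neck_length,
                 liner_thickness = liner_thickness,
                 shaft_radius = shaft_radius, shaft_start = shaft_start,
                 shaft_end = shaft_end, plate_distance = plate_distance,
                 plate_half_width = plate_half_width,
                 plate_thickness = plate_thickness, bump = bump,
                 mesh_edge_length = mesh_edge_length,
                 random_seed = as.integer(random_seed)),
            class = "fixture_spec")
}

## ---- primitive meshers ----------------------------------------------------

# grid-of-quads triangulation helper: rows of vertex ids (closed in phi)
.stitch_rings <- function(ring_a, ring_b) {
  n <- length(ring_a)
  j <- seq_len(n)
  jn <- c(seq_len(n)[-1], 1L)
  rbind(cbind(ring_a[j], ring_a[jn], ring_b[j]),
        cbind(ring_a[jn], ring_b[jn], ring_b[j]))
}

.fan <- function(center_id, ring, reverse = FALSE) {
  n <- length(ring)
  jn <- c(seq_len(n)[-1], 1L)
  f <- cbind(center_id, ring, ring[jn])
  if (reverse) f[, c(1L, 3L, 2L)] else f
}

.ring_points <- function(r, z, n_phi) {
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  cbind(r * cos(phi), r * sin(phi), z)
}

# UV sphere, outward-oriented
.mesh_sphere <- function(radius, center, edge) {
  n_th <- max(8L, ceiling(pi * radius / edge))
  n_phi <- max(12L, ceiling(2 * pi * radius / edge))
  th <- pi * seq_len(n_th - 1L) / n_th
  verts <- rbind(c(0, 0, radius))
  rings <- list()
  for (t in th) {
    rings[[length(rings) + 1L]] <- nrow(verts) + seq_len(n_phi)
    verts <- rbind(verts, .ring_points(radius * sin(t), radius * cos(t),
                                       n_phi))
  }
  verts <- rbind(verts, c(0, 0, -radius))
  bot <- nrow(verts)
  faces <- .fan(1L, rings[[1]], reverse = TRUE)
  for (i in seq_len(length(rings) - 1L))
    faces <- rbind(faces, .stitch_rings(rings[[i]], rings[[i + 1L]]))
  faces <- rbind(faces, .fan(bot, rings[[length(rings)]]))
  list(vertices = sweep(verts, 2L, center, "+"), faces = faces)
}

# capped cylinder from p0 to p1 (axis along p1 - p0), outward-oriented
.mesh_cylinder <- function(radius, p0, p1, edge) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  w <- axis / len
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * w) * w
  u <- u / sqrt(sum(u^2))
  v <- .cross3(w, u)
  n_phi <- max(12L, ceiling(2 * pi * radius / edge))
  n_len <- max(1L, ceiling(len / edge))
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  circ <- outer(cos(phi), u) + outer(sin(phi), v)
  verts <- matrix(numeric(0), 0L, 3L)
  rings <- list()
  for (i in 0:n_len) {
    base <- p0 + (i / n_len) * axis
    rings[[i + 1L]] <- nrow(verts) + seq_len(n_phi)
    verts <- rbind(verts, sweep(radius * circ, 2L, base, "+"))
  }
  faces <- NULL
  for (i in seq_len(n_len))
    faces <- rbind(faces, .stitch_rings(rings[[i]], rings[[i + 1L]]))
  verts <- rbind(verts, p0, p1)
  c0 <- nrow(verts) - 1L
  c1 <- nrow(verts)
  faces <- rbind(faces, .fan(c0, rings[[1]]),
                 .fan(c1, rings[[n_len + 1L]], reverse = TRUE))
  list(vertices = verts, faces = faces)
}

# spherical-cap shell: inner radius r, thickness th, opening half-angle
# beta (deg) about -z, centred at the origin; closed by a rim annulus
.mesh_shell_cap <- function(r, th, beta_deg, edge) {
  beta <- beta_deg * pi / 180
  span <- pi - beta
  r_out <- r + th
  n_phi <- max(16L, ceiling(2 * pi * r_out / edge))
  surf <- function(radius) {
    n_g <- max(4L, ceiling(span * radius / edge))
    g <- beta + span * (0:(n_g - 1L)) / n_g
    verts <- matrix(numeric(0), 0L, 3L)
    rings <- list()
    for (gg in g) {
      rings[[length(rings) + 1L]] <- nrow(verts) + seq_len(n_phi)
      verts <- rbind(verts,
                     .ring_points(radius * sin(gg), -radius * cos(gg),
                                  n_phi))
    }
    verts <- rbind(verts, c(0, 0, radius))   # pole at gamma = pi
    list(verts = verts, rings = rings, pole = nrow(verts))
  }
  si <- surf(r)
  so <- surf(r_out)
  verts <- rbind(si$verts, so$verts)
  off <- nrow(si$verts)
  faces <- NULL
  # inner surface: normals toward the origin (outward from the material)
  for (i in seq_len(length(si$rings) - 1L))
    faces <- rbind(faces, .stitch_rings(si$rings[[i + 1L]], si$rings[[i]]))
  faces <- rbind(faces, .fan(si$pole, si$rings[[length(si$rings)]]))
  # outer surface: normals away from the origin
  for (i in seq_len(length(so$rings) - 1L))
    faces <- rbind(faces, .stitch_rings(off + so$rings[[i]],
                                        off + so$rings[[i + 1L]]))
  faces <- rbind(faces, .fan(off + so$pole,
                             off + so$rings[[length(so$rings)]],
                             reverse = TRUE))
  # rim annulus joining the two opening rings
  faces <- rbind(faces, .stitch_rings(si$rings[[1L]], off + so$rings[[1L]]))
  list(vertices = verts, faces = faces)
}

# axis-aligned-in-(u,v,w) box plate facing the origin along -u
.mesh_plate <- function(u, dist, half_width, thickness, edge) {
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- ref - sum(ref * u) * u
  a <- a / sqrt(sum(a^2))
  b <- .cross3(u, a)
  n <- max(2L, ceiling(2 * half_width / edge))
  s <- seq(-half_width, half_width, length.out = n + 1L)
  grid_face <- function(d, flip) {
    verts <- matrix(numeric(0), 0L, 3L)
    idx <- matrix(0L, n + 1L, n + 1L)
    for (i in seq_len(n + 1L)) for (j in seq_len(n + 1L)) {
      verts <- rbind(verts, d * u + s[i] * a + s[j] * b)
      idx[i, j] <- nrow(verts)
    }
    faces <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      q <- c(idx[i, j], idx[i + 1L, j], idx[i + 1L, j + 1L], idx[i, j + 1L])
      f2 <- rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
      if (flip) f2 <- f2[, c(1L, 3L, 2L)]
      faces <- rbind(faces, f2)
    }
    list(verts = verts, faces = faces, idx = idx)
  }
  # front face normal points toward the origin (-u), back face +u
  front <- grid_face(dist, flip = TRUE)
  back <- grid_face(dist + thickness, flip = FALSE)
  verts <- rbind(front$verts, back$verts)
  off <- nrow(front$verts)
  faces <- rbind(front$faces, back$faces + off)
  ring_f <- c(front$idx[, 1L], front$idx[n + 1L, -1L],
              rev(front$idx[-(n + 1L), n + 1L]),
              rev(front$idx[1L, ])[-c(1L, n + 1L)])
  ring_b <- ring_f + off
  faces <- rbind(faces, .stitch_rings(ring_f, ring_b))
  list(vertices = verts, faces = faces)
}

# Make winding consistent within each component (propagating the rule that
# a shared edge must run in opposite directions in its two faces), then
# orient every closed component outward (positive signed volume).
.orient_outward <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  ef <- mesh$edge_faces
  nbr <- vector("list", m)
  for (i in which(!is.na(ef[, 2]))) {
    nbr[[ef[i, 1]]] <- c(nbr[[ef[i, 1]]], ef[i, 2])
    nbr[[ef[i, 2]]] <- c(nbr[[ef[i, 2]]], ef[i, 1])
  }
  has_directed <- function(face, a, b) {
    (face[1] == a && face[2] == b) || (face[2] == a && face[3] == b) ||
      (face[3] == a && face[1] == b)
  }
  shared_edge <- function(fa, fb) {
    common <- intersect(fa, fb)
    common[1:2]
  }
  seen <- logical(m)
  for (s in seq_len(m)) {
    if (seen[s]) next
    seen[s] <- TRUE
    comp <- s
    queue <- s
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (g in nbr[[cur]]) {
        if (seen[g]) next
        seen[g] <- TRUE
        se <- shared_edge(f[cur, ], f[g, ])
        # find the direction the edge takes in cur, require opposite in g
        if (has_directed(f[cur, ], se[1], se[2])) {
          if (has_directed(f[g, ], se[1], se[2])) f[g, ] <- f[g, c(1, 3, 2)]
        } else {
          if (has_directed(f[g, ], se[2], se[1])) f[g, ] <- f[g, c(1, 3, 2)]
        }
        comp <- c(comp, g)
        queue <- c(queue, g)
      }
    }
    v <- mesh$vertices
    a <- v[f[comp, 1], , drop = FALSE]
    b <- v[f[comp, 2], , drop = FALSE]
    c3 <- v[f[comp, 3], , drop = FALSE]
    det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
    if (sum(det6) < 0) f[comp, ] <- f[comp, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh$faces <- f
  .build_adjacency(mesh)
}

.as_trimesh <- function(prim) {
  m <- trimesh(prim$vertices, prim$faces, weld_tolerance = 1e-6)
  .orient_outward(m)
}

## ---- fixture assembly -----------------------------------------------------

#' Build a hip model from a fixture specification
#'
#' Deterministic: the same spec always yields bit-identical meshes.  The
#' model is PI-free at the neutral posture by construction.
#'
#' @param spec a [fixture_spec].
#' @return A [hip_model] with `hip_center = (0,0,0)` and the neutral
#'   femoral axis along -z.
#' @export
make_hip_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  e <- spec$mesh_edge_length
  liner <- .as_trimesh(.mesh_shell_cap(spec$cup_radius,
                                       spec$liner_thickness,
                                       spec$rim_opening_half_angle, e))
  head <- .mesh_sphere(spec$head_radius, c(0, 0, 0), e)
  neck <- .mesh_cylinder(spec$neck_radius, c(0, 0, 0),
                         c(0, 0, -spec$neck_length), e)
  stem <- .as_trimesh(list(vertices = rbind(head$vertices, neck$vertices),
                           faces = rbind(head$faces,
                                         neck$faces + nrow(head$vertices))))
  femur <- .as_trimesh(.mesh_cylinder(spec$shaft_radius,
                                      c(0, 0, -spec$shaft_start),
                                      c(0, 0, -spec$shaft_end), e))
  u <- if (is.null(spec$bump)) c(1, 0, 0) else
    spec$bump$direction / sqrt(sum(spec$bump$direction^2))
  plate <- .mesh_plate(u, spec$plate_distance, spec$plate_half_width,
                       spec$plate_thickness, e)
  if (!is.null(spec$bump)) {
    ctr <- u * (spec$plate_distance - spec$bump$height + spec$bump$radius)
    bump <- .mesh_sphere(spec$bump$radius, ctr, min(e, spec$bump$radius))
    plate <- list(vertices = rbind(plate$vertices, bump$vertices),
                  faces = rbind(plate$faces,
                                bump$faces + nrow(plate$vertices)))
  }
  pelvis <- .as_trimesh(plate)
  hip_model(pelvis = pelvis, femur = femur, stem = stem, liner = liner,
            hip_center = c(0, 0, 0), femur_axis_point = c(0, 0, -100),
            side = "right")
}

## ---- closed-form contact oracles ------------------------------------------

#' Analytic rim-contact tilt of the neck
#'
#' Closed-form tilt (degrees, from the cup axis) at which the cylindrical
#' neck first touches the liner's inner rim circle.  Derivation: the rim
#' circle has radius `R sin(beta)` at polar angle `beta` from the cup
#' axis, where `R = cup_radius` and `beta = rim_opening_half_angle`; when
#' the neck axis is tilted by `t` towards an azimuth, the rim point at that
#' azimuth subtends the angle `beta - t` with the axis, so its distance to
#' the axis is `R sin(beta - t)`.  Contact occurs when this equals the neck
#' radius `r`:
#'
#'   t* = beta - asin(r / R).
#'
#' The fixture is axisymmetric, so the angle is azimuth-independent; the
#' `azimuth` argument exists for interface symmetry with swept checks.
#' As r -> 0 the angle tends to `beta` (line-against-rim limit), and it
#' strictly decreases with the neck radius.
#'
#' @param spec a [fixture_spec].
#' @param azimuth azimuth in degrees (unused for this axisymmetric
#'   fixture).
#' @return Contact tilt in degrees.
#' @export
analytic_rim_contact <- function(spec, azimuth = 0) {
  stopifnot(inherits(spec, "fixture_spec"))
  ratio <- spec$neck_radius / spec$cup_radius
  if (ratio >= 1) stop("geometrically impossible: neck wider than cup")
  t_star <- spec$rim_opening_half_angle - asin(ratio) * 180 / pi
  if (t_star <= 0)
    stop("geometrically impossible: neck already contacts the rim ",
         "at the neutral pose")
  s_axial <- sqrt(spec$cup_radius^2 - spec$neck_radius^2)
  if (s_axial > spec$neck_length)
    stop("geometrically impossible: neck too short to reach the rim")
  t_star
}

#' Analytic tilt at which the femur proxy reaches the bump
#'
#' Closed-form tilt (degrees) at which the shaft surface first meets the
#' pelvis bump.  With the bump sphere (radius `rb`) centred at distance
#' `D` from the hip centre, at polar angle `gamma` from the neutral -z
#' axis, and the shaft of radius `rs` along the femoral axis, the
#' centre-to-axis distance after tilting by `t` towards the bump azimuth is
#' `D sin(gamma - t)`; contact occurs when it equals `rs + rb`:
#'
#'   t_reach = gamma - asin((rs + rb) / D).
#'
#' A non-positive value means the neutral posture already contacts the
#' bump.  `Inf` is returned when the bump cannot be reached (contact point
#' outside the shaft's axial span, or a tilt beyond 90 degrees would be
#' needed, e.g. a bump behind the plate).
#'
#' @param spec a [fixture_spec] with a bump.
#' @param surface `"femur"` (shaft, default) or `"stem"` (neck).
#' @return Reach tilt in degrees, or `Inf` if unreachable.
#' @export
analytic_bump_reach <- function(spec, surface = c("femur", "stem")) {
  stopifnot(inherits(spec, "fixture_spec"))
  surface <- match.arg(surface)
  if (is.null(spec$bump)) stop("fixture has no bump")
  u <- spec$bump$direction / sqrt(sum(spec$bump$direction^2))
  D <- spec$plate_distance - spec$bump$height + spec$bump$radius
  gamma <- acos(sum(u * c(0, 0, -1))) * 180 / pi
  rs <- if (surface == "femur") spec$shaft_radius else spec$neck_radius
  span <- if (surface == "femur") c(spec$shaft_start, spec$shaft_end)
  else c(0, spec$neck_length)
  rsum <- rs + spec$bump$radius
  if (rsum >= D)
    stop("invalid bump: sphere overlaps the femoral axis region")
  s_axial <- sqrt(D^2 - rsum^2)
  if (s_axial < span[1] || s_axial > span[2]) return(Inf)
  t_reach <- gamma - asin(rsum / D) * 180 / pi
  if (t_reach > 90) return(Inf)
  t_reach
}

#' Write fixture meshes and a ready-to-run configuration
#'
#' Writes the four STL meshes plus a YAML run configuration referring to
#' them, so a fixture can be driven through the full pipeline (or the
#' command-line interface) like patient data.
#'
#' @param spec a [fixture_spec].
#' @param dir output directory (created if needed).
#' @return The config file path, invisibly.
#' @export
write_fixture_set <- function(spec, dir) {
  model <- make_hip_fixture(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("pelvis", "femur", "stem", "liner"))
    write_stl(model[[nm]], file.path(dir, paste0(nm, ".stl")))
  cfg <- list(
    meshes = as.list(stats::setNames(
      file.path(dir, paste0(c("pelvis", "femur", "stem", "liner"), ".stl")),
      c("pelvis", "femur", "stem", "liner"))),
    hip_center = model$hip_center,
    femur_axis_point = model$femur_axis_point,
    side = model$side,
    sweep = list(dt_pos = 5, dt_alpha = 1, n_alpha = 61, dt_con = 10),
    fixture_seed = spec$random_seed)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
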