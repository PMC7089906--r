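#' Indexed triangle surface mesh
#'
#' Constructs a `trimesh`: a welded, indexed triangle surface with edge
#' adjacency, the unit all geometric operations in this package act on.
#' Coordinates are millimetres throughout.
#'
#' Duplicate vertices closer than `weld_tolerance` are merged so that
#' interior edges are shared by exactly two faces; STL stores facets with no
#' connectivity, and region growing requires shared edges, so welding is
#' mandatory on load.  Degenerate (zero-area) faces are rejected.
#'
#' @param vertices numeric matrix, one 3D point per row (mm).
#' @param faces integer matrix, one triple of 1-based vertex indices per row.
#' @param weld_tolerance vertices closer than this (mm) are merged.
#'   Use 0 to skip welding.
#' @return An object of class `trimesh` with components `vertices`, `faces`,
#'   `edges` (E x 2, sorted vertex pairs), `edge_faces` (E x 2, the 1-2 faces
#'   sharing each edge, `NA` for border edges) and `face_edges` (m x 3).
#' @export
trimesh <- function(vertices, faces, weld_tolerance = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (length(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face index out of range")
  }
  if (weld_tolerance > 0 && nrow(vertices) > 0L) {
    key <- paste(round(vertices[, 1] / weld_tolerance),
                 round(vertices[, 2] / weld_tolerance),
                 round(vertices[, 3] / weld_tolerance))
    keep <- !duplicated(key)
    map <- match(key, key[keep])
    vertices <- vertices[keep, , drop = FALSE]
    if (nrow(faces) > 0L) faces <- matrix(map[faces], ncol = 3L)
  }
  if (nrow(faces) > 0L) {
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    a2 <- .tri_areas(vertices, faces)
    degen <- degen | a2 <= 1e-12
    if (any(degen))
      stop("degenerate (zero-area) facet(s): ",
           paste(utils::head(which(degen), 5L), collapse = ", "))
  }
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "trimesh")
  .build_adjacency(mesh)
}

# triangle areas (mm^2), vectorised
.tri_areas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

.build_adjacency <- function(mesh) {
  faces <- mesh$faces
  m <- nrow(faces)
  if (m == 0L) {
    mesh$edges <- matrix(integer(0), 0L, 2L)
    mesh$edge_faces <- matrix(integer(0), 0L, 2L)
    mesh$face_edges <- matrix(integer(0), 0L, 3L)
    return(mesh)
  }
  ea <- rbind(faces[, c(1L, 2L), drop = FALSE],
              faces[, c(2L, 3L), drop = FALSE],
              faces[, c(3L, 1L), drop = FALSE])
  es <- cbind(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  nv <- nrow(mesh$vertices)
  key <- as.numeric(es[, 1]) * (nv + 1) + as.numeric(es[, 2])
  ukey <- key[!duplicated(key)]
  eid <- match(key, ukey)
  ne <- length(ukey)
  edges <- es[!duplicated(key), , drop = FALSE]
  fidx <- rep.int(seq_len(m), 3L)
  ef <- matrix(NA_integer_, ne, 2L)
  first <- !duplicated(eid)
  ef[eid[first], 1L] <- fidx[first]
  rest <- which(!first)
  second <- rest[!duplicated(eid[rest])]
  ef[eid[second], 2L] <- fidx[second]
  cnt <- tabulate(eid, ne)
  if (any(cnt > 2L))
    warning(sum(cnt > 2L), " non-manifold edge(s) shared by >2 faces")
  mesh$edges <- edges
  mesh$edge_faces <- ef
  mesh$face_edges <- matrix(eid, ncol = 3L)
  mesh
}

#' @export
print.trimesh <- function(x, ...) {
  cat("trimesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces,",
      nrow(x$edges), "edges\n")
  if (nrow(x$faces) > 0L) {
    b <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                b[1, 1], b[2, 1], b[1, 2], b[2, 2], b[1, 3], b[2, 3]))
    cat(sprintf("  area %.2f mm^2, %s\n", face_area(x),
                if (is_closed(x)) "closed" else "open"))
  }
  invisible(x)
}

#' Total area of a set of faces
#'
#' Sum of triangle areas (half cross-product magnitude) over `face_ids`.
#'
#' @param mesh a [trimesh].
#' @param face_ids integer face ids; `NULL` (default) sums all faces.  An
#'   empty set gives 0.
#' @return Area in mm^2.
#' @export
face_area <- function(mesh, face_ids = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  if (is.null(face_ids)) face_ids <- seq_len(nrow(mesh$faces))
  if (length(face_ids) == 0L) return(0)
  face_ids <- as.integer(face_ids)
  if (anyNA(face_ids) || any(face_ids < 1L | face_ids > nrow(mesh$faces)))
    stop("invalid face id")
  sum(.tri_areas(mesh$vertices, mesh$faces[face_ids, , drop = FALSE]))
}

#' Is a mesh closed (watertight)?
#'
#' TRUE when every edge is shared by exactly two faces.  Containment tests
#' require a closed opposing mesh; open meshes trigger the documented
#' area-based fallback in [select_impinged()].
#' @param mesh a [trimesh].
#' @export
is_closed <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  !anyNA(mesh$edge_faces[, 2L])
}

#' Mirror a mesh about the sagittal (y = 0) plane
#'
#' Left-side hips are mirrored on load so all internal maths assumes a right
#' hip; outputs are mirrored back on save.  Face winding is flipped so the
#' mesh stays outward-oriented; face and vertex ids are unchanged.
#' @param mesh a [trimesh].
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 2] <- -v[, 2]
  m <- mesh
  m$vertices <- v
  m$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  .build_adjacency(m)
}

#' Mirror a 3D point (or matrix of points) about the sagittal plane
#' @param p numeric length-3 vector or n x 3 matrix.
#' @export
mirror_point <- function(p) {
  if (is.matrix(p)) { p[, 2] <- -p[, 2]; p } else { p * c(1, -1, 1) }
}

#' Median edge length of a mesh (mm)
#' @param mesh a [trimesh].
#' @export
median_edge_length <- function(mesh) {
  if (nrow(mesh$edges) == 0L) return(NA_real_)
  d <- mesh$vertices[mesh$edges[, 1], , drop = FALSE] -
    mesh$vertices[mesh$edges[, 2], , drop = FALSE]
  stats::median(sqrt(rowSums(d^2)))
}

# connected components of faces over shared edges; returns integer label/face
.face_components <- function(mesh) {
  m <- nrow(mesh$faces)
  lab <- integer(m)
  ef <- mesh$edge_faces
  nbr <- vector("list", m)
  both <- !is.na(ef[, 2])
  for (i in which(both)) {
    nbr[[ef[i, 1]]] <- c(nbr[[ef[i, 1]]], ef[i, 2])
    nbr[[ef[i, 2]]] <- c(nbr[[ef[i, 2]]], ef[i, 1])
  }
  comp <- 0L
  for (s in seq_len(m)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      f <- queue[[1]]
      queue <- queue[-1]
      for (g in nbr[[f]]) if (lab[g] == 0L) { lab[g] <- comp; queue <- c(queue, g) }
    }
  }
  lab
}
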