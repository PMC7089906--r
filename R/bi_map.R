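#' Clearance severity categories
#'
#' Each posture's clearance angle is divided into bands at the given
#' fractions; bony contact within a smaller fraction of the clearance is a
#' higher impingement risk.  Defaults: 25/50/75/100 % coloured
#' red/yellow/green/blue (most to least severe).
#'
#' @param fractions strictly increasing values in (0, 1].
#' @param colors one colour name per fraction.
#' @param non_impinged colour for unflagged faces.
#' @export
cca_categories <- function(fractions = c(0.25, 0.50, 0.75, 1.00),
                           colors = c("red", "yellow", "green", "blue"),
                           non_impinged = "grey") {
  if (length(fractions) != length(colors))
    stop("fractions and colors must have the same length")
  if (any(fractions <= 0) || any(fractions > 1) ||
      any(diff(fractions) <= 0))
    stop("fractions must be strictly increasing in (0, 1]")
  structure(list(fractions = fractions, colors = colors,
                 non_impinged = non_impinged),
            class = "cca_categories")
}

#' Category angle thresholds for one clearance angle
#'
#' Returns `fraction * cca` for each fraction, in order, e.g. a 20 degree
#' clearance with the default fractions gives 5, 10, 15, 20 degrees.
#' @param cca clearance angle in degrees (>= 0).
#' @param categories a [cca_categories].
#' @export
categorize <- function(cca, categories = cca_categories()) {
  if (cca < 0) stop("cca must be >= 0")
  categories$fractions * cca
}

#' Seed/child region growing over a triangle mesh
#'
#' Clusters the mesh faces bounded by an intersection curve.  A face is a
#' *seed* iff none of its three vertices is crossed (all its vertices lie
#' in one region); growth proliferates child faces across shared edges
#' between seed faces and stops at the crossing curve.  Faces touching a
#' crossed vertex straddle the boundary and belong to no cluster, so each
#' grown region is slightly smaller than the true bounded area (negligible
#' for fine meshes).  The start face is the lowest-index seed of each
#' component, which makes the result reproducible; membership is in fact
#' independent of the start face.
#'
#' @param mesh a [trimesh].
#' @param crossed_vertices integer vertex ids on the intersection boundary
#'   (e.g. `crossed_vertices_b` of a [mesh_intersect()] result).
#' @return List of clusters (integer face-id vectors, each sorted, ordered
#'   by their smallest face id), with attribute `"unassigned"` holding the
#'   boundary-straddling faces.
#' @export
region_grow <- function(mesh, crossed_vertices) {
  stopifnot(inherits(mesh, "trimesh"))
  m <- nrow(mesh$faces)
  crossed_vertices <- as.integer(crossed_vertices)
  if (length(crossed_vertices) &&
      (anyNA(crossed_vertices) || min(crossed_vertices) < 1L ||
       max(crossed_vertices) > nrow(mesh$vertices)))
    stop("invalid crossed vertex id")
  vflag <- logical(nrow(mesh$vertices))
  vflag[crossed_vertices] <- TRUE
  seed <- !(vflag[mesh$faces[, 1]] | vflag[mesh$faces[, 2]] |
              vflag[mesh$faces[, 3]])
  # adjacency restricted to seed faces
  ef <- mesh$edge_faces
  ok <- !is.na(ef[, 2])
  ok[ok] <- seed[ef[ok, 1]] & seed[ef[ok, 2]]
  nbr <- vector("list", m)
  for (i in which(ok)) {
    nbr[[ef[i, 1]]] <- c(nbr[[ef[i, 1]]], ef[i, 2])
    nbr[[ef[i, 2]]] <- c(nbr[[ef[i, 2]]], ef[i, 1])
  }
  assigned <- !seed          # straddling faces never enter a cluster
  clusters <- list()
  for (s in seq_len(m)) {
    if (assigned[s]) next
    members <- integer(0)
    frontier <- s            # current generation of seed faces
    assigned[s] <- TRUE
    while (length(frontier)) {
      members <- c(members, frontier)
      children <- integer(0) # next generation grown across shared edges
      for (f in frontier) {
        for (g in nbr[[f]]) {
          if (!assigned[g]) { assigned[g] <- TRUE; children <- c(children, g) }
        }
      }
      frontier <- children
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
  }
  structure(clusters, unassigned = which(!seed))
}

#' Select the impinged clusters
#'
#' Decides which region-grown clusters are the impinged (penetrated) side
#' of the crossing.  A cluster is impinged iff a representative interior
#' point -- the centroid of its largest face offset inward (against the
#' face normal) by 0.1 x the median edge length -- lies inside the opposing
#' closed mesh by ray parity.  If the opposing mesh is open, the fallback
#' marks every boundary-adjacent cluster that is smaller in area than its
#' neighbour across the straddling band, with a warning.
#'
#' @param clusters result of [region_grow()] (with a non-empty crossing).
#' @param mesh the [trimesh] the clusters live on.
#' @param other the opposing [trimesh].
#' @param other_transform optional pose of the opposing mesh.
#' @param mesh_transform optional pose of `mesh` itself (the representative
#'   points are tested in world coordinates).
#' @return Integer face ids of all impinged clusters (possibly empty).
#' @export
select_impinged <- function(clusters, mesh, other, other_transform = NULL,
                            mesh_transform = NULL) {
  if (length(attr(clusters, "unassigned")) == 0L)
    stop("clusters carry no crossing boundary; nothing to select")
  if (length(clusters) == 0L) return(integer(0))
  v <- mesh$vertices
  if (!is.null(mesh_transform)) v <- tf_apply(mesh_transform, v)
  if (is_closed(other)) {
    eps <- 0.1 * median_edge_length(mesh)
    picked <- vapply(clusters, function(cl) {
      ar <- .tri_areas(v, mesh$faces[cl, , drop = FALSE])
      f <- cl[which.max(ar)]
      tri <- v[mesh$faces[f, ], , drop = FALSE]
      ctr <- colMeans(tri)
      n <- .cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      n <- n / sqrt(sum(n^2))
      point_in_mesh(ctr - eps * n, other, transform = other_transform)
    }, logical(1))
    return(sort(unlist(clusters[picked], use.names = FALSE)))
  }
  warning("opposing mesh is not closed; using the area-based fallback ",
          "to pick impinged clusters")
  strad <- attr(clusters, "unassigned")
  lab <- rep.int(0L, nrow(mesh$faces))
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  # link clusters through connected runs of straddling faces
  ef <- mesh$edge_faces
  ok <- !is.na(ef[, 2])
  links <- lapply(seq_along(clusters), function(i) integer(0))
  sset <- logical(nrow(mesh$faces)); sset[strad] <- TRUE
  scomp <- .straddle_components(mesh, strad)
  for (ci in seq_along(scomp)) {
    touched <- integer(0)
    for (f in scomp[[ci]]) {
      adj <- c(ef[mesh$face_edges[f, ], 1L], ef[mesh$face_edges[f, ], 2L])
      adj <- adj[!is.na(adj)]
      touched <- c(touched, lab[adj[lab[adj] > 0L]])
    }
    touched <- unique(touched)
    for (i in touched) links[[i]] <- union(links[[i]], setdiff(touched, i))
  }
  areas <- vapply(clusters, function(cl) face_area(mesh, cl), numeric(1))
  picked <- vapply(seq_along(clusters), function(i) {
    length(links[[i]]) > 0L && areas[i] < max(areas[links[[i]]])
  }, logical(1))
  sort(unlist(clusters[picked], use.names = FALSE))
}

# connected components within the straddling faces (shared-edge adjacency)
.straddle_components <- function(mesh, strad) {
  inset <- logical(nrow(mesh$faces)); inset[strad] <- TRUE
  ef <- mesh$edge_faces
  ok <- !is.na(ef[, 2])
  ok[ok] <- inset[ef[ok, 1]] & inset[ef[ok, 2]]
  nbr <- list()
  for (i in which(ok)) {
    a <- ef[i, 1]; b <- ef[i, 2]
    nbr[[as.character(a)]] <- c(nbr[[as.character(a)]], b)
    nbr[[as.character(b)]] <- c(nbr[[as.character(b)]], a)
  }
  seen <- logical(nrow(mesh$faces))
  comps <- list()
  for (s in strad) {
    if (seen[s]) next
    seen[s] <- TRUE
    queue <- s; members <- integer(0)
    while (length(queue)) {
      f <- queue[[1]]; queue <- queue[-1]
      members <- c(members, f)
      for (g in nbr[[as.character(f)]])
        if (!seen[g]) { seen[g] <- TRUE; queue <- c(queue, g) }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

#' Map bony impingement within the clearance cone
#'
#' For every posture of every profile, sweeps the conical motion at
#' apertures `0, dt_alpha, ...` up to that posture's clearance angle and
#' records, at each pose where the moving surface crosses the bone, the
#' crossing faces plus their region-grown impinged clusters.  Mode
#' `"BTBI"` intersects the femur with the pelvis (both sides recorded);
#' mode `"ITBI"` intersects the stem with the pelvis.  Severity: a face
#' keeps the smallest aperture fraction at which it was ever flagged
#' (categories nest, so the most severe colour always wins).
#'
#' @param model a [hip_model].
#' @param profiles a `cca_profile` or list of them, computed on `model`
#'   with the same `params`.
#' @param categories a [cca_categories].
#' @param params the [sweep_params] the profiles were computed with.
#' @param mode `"BTBI"` or `"ITBI"`.
#' @return For BTBI a list `(pelvis, femur)` of `impingement_map`s; for
#'   ITBI a list `(pelvis)`.
#' @export
map_impingement <- function(model, profiles, categories = cca_categories(),
                            params = sweep_params(),
                            mode = c("BTBI", "ITBI")) {
  mode <- match.arg(mode)
  if (inherits(profiles, "cca_profile")) profiles <- list(profiles)
  moving <- if (mode == "BTBI") model$femur else model$stem
  static <- model$pelvis
  if (nrow(moving$faces) == 0L || nrow(static$faces) == 0L)
    stop("mode ", mode, " requires non-empty meshes")
  a0 <- model$femur_axis_point - model$hip_center
  a0 <- a0 / sqrt(sum(a0^2))
  ev_static <- list()   # events: list(faces, ratio, activity, posture)
  ev_moving <- list()
  for (prof in profiles) {
    postures <- attr(prof, "postures")
    if (is.null(postures) || length(postures) != nrow(prof))
      stop("profile does not carry its postures; ",
           "was it computed by compute_cca_profile()?")
    act <- attr(prof, "activity")
    for (i in seq_len(nrow(prof))) {
      cca_i <- prof$cca_deg[i]
      ptf <- posture_transform(postures[[i]], model)
      axis <- as.numeric(ptf$R %*% a0)
      alphas <- seq(0, cca_i, by = params$dt_alpha)
      for (alpha in alphas) {
        cones <- conical_positions(axis, alpha, params$dt_con,
                                   model$hip_center)
        if (alpha == 0) cones <- cones[1L]
        ratio <- if (cca_i > 0) alpha / cca_i else 0
        for (tf in cones) {
          pose <- tf_compose(tf, ptf)
          res <- mesh_intersect(moving, static, transform_a = pose)
          if (!res$intersects) next
          cl_s <- region_grow(static, res$crossed_vertices_b)
          imp_s <- select_impinged(cl_s, static, moving,
                                   other_transform = pose)
          faces_s <- union(res$crossed_faces_b, imp_s)
          ev_static[[length(ev_static) + 1L]] <-
            list(faces = faces_s, ratio = ratio, activity = act, posture = i)
          if (mode == "BTBI") {
            cl_m <- region_grow(moving, res$crossed_vertices_a)
            imp_m <- select_impinged(cl_m, moving, static,
                                     mesh_transform = pose)
            faces_m <- union(res$crossed_faces_a, imp_m)
            ev_moving[[length(ev_moving) + 1L]] <-
              list(faces = faces_m, ratio = ratio, activity = act,
                   posture = i)
          }
        }
      }
    }
  }
  out <- list(pelvis = .events_to_map("pelvis", mode, nrow(static$faces),
                                      ev_static, categories))
  if (mode == "BTBI")
    out$femur <- .events_to_map("femur", mode, nrow(moving$faces),
                                ev_moving, categories)
  out
}

.events_to_map <- function(bone, mode, n_faces, events, categories) {
  ratio <- rep.int(Inf, n_faces)
  prov <- list()
  for (ev in events) {
    f <- ev$faces
    ratio[f] <- pmin(ratio[f], ev$ratio)
    prov[[length(prov) + 1L]] <-
      data.frame(face = f, activity = ev$activity, posture = ev$posture)
  }
  prov <- if (length(prov)) unique(do.call(rbind, prov))
  else data.frame(face = integer(0), activity = character(0),
                  posture = integer(0))
  structure(list(bone = bone, mode = mode, n_faces = n_faces,
                 ratio = ratio,
                 category = .collapse_category(ratio, categories),
                 provenance = prov[order(prov$face), , drop = FALSE],
                 categories = categories),
            class = "impingement_map")
}

# severity collapse: smallest fraction whose band contains the face's
# minimal flagged aperture ratio (1e-9 slack absorbs binary fractions)
.collapse_category <- function(ratio, categories) {
  cat <- integer(length(ratio))
  flagged <- is.finite(ratio)
  fr <- categories$fractions
  cat[flagged] <- vapply(ratio[flagged], function(r)
    which(r <= fr + 1e-9)[1L], integer(1))
  cat
}

#' @export
print.impingement_map <- function(x, ...) {
  cat(sprintf("impingement_map: %s on %s (%d faces)\n", x$mode, x$bone,
              x$n_faces))
  n <- tabulate(x$category, length(x$categories$fractions))
  for (j in seq_along(n))
    cat(sprintf("  %-7s (<= %3.0f%% CCA): %d faces\n",
                x$categories$colors[j], 100 * x$categories$fractions[j],
                n[j]))
  cat("  non-impinged:", sum(x$category == 0L), "faces\n")
  invisible(x)
}

#' Pre-collapse impinged face set at a clearance fraction
#'
#' Faces flagged at any aperture up to `fraction` of the per-posture
#' clearance.  These sets nest: the set at 25 % is contained in the set at
#' any larger fraction.
#' @param map an `impingement_map`.
#' @param fraction clearance fraction in (0, 1].
#' @export
itf_faces <- function(map, fraction) {
  which(map$ratio <= fraction + 1e-9)
}

#' Remove infeasible implant-to-bone contacts
#'
#' Pelvis faces flagged by both the BTBI and the ITBI analysis are contacts
#' of the stem region buried in the femoral canal (covered by bone) and
#' cannot occur; they are reset to non-impinged in the ITBI map.  The BTBI
#' map is unchanged.
#'
#' @param itbi,btbi pelvis `impingement_map`s from [map_impingement()].
#' @return The filtered ITBI map (attribute `"filtered_faces"` lists the
#'   removed faces).
#' @export
filter_itbi <- function(itbi, btbi) {
  stopifnot(inherits(itbi, "impingement_map"),
            inherits(btbi, "impingement_map"))
  if (itbi$bone != btbi$bone)
    stop("maps are on different bones: ", itbi$bone, " vs ", btbi$bone)
  common <- which(itbi$category > 0L & btbi$category > 0L)
  out <- itbi
  out$ratio[common] <- Inf
  out$category[common] <- 0L
  out$provenance <- out$provenance[!(out$provenance$face %in% common), ,
                                   drop = FALSE]
  attr(out, "filtered_faces") <- common
  out
}

#' Combine ITBI and BTBI maps on one bone
#'
#' Per face, the more severe (smaller fraction) of the two maps wins;
#' provenance is merged.  Commutative and idempotent.
#' @param itbi,btbi `impingement_map`s on the same bone.
#' @export
combine_maps <- function(itbi, btbi) {
  stopifnot(inherits(itbi, "impingement_map"),
            inherits(btbi, "impingement_map"))
  if (itbi$bone != btbi$bone)
    stop("maps are on different bones: ", itbi$bone, " vs ", btbi$bone)
  if (itbi$n_faces != btbi$n_faces) stop("maps disagree on face count")
  out <- itbi
  out$mode <- "combined"
  out$ratio <- pmin(itbi$ratio, btbi$ratio)
  out$category <- .collapse_category(out$ratio, itbi$categories)
  out$provenance <- unique(rbind(itbi$provenance, btbi$provenance))
  out$provenance <- out$provenance[order(out$provenance$face), ,
                                   drop = FALSE]
  out
}

#' Face colour names for a map
#' @param map an `impingement_map`.
#' @return Character vector, one palette colour name per face.
#' @export
map_face_colors <- function(map) {
  cols <- c(map$categories$non_impinged, map$categories$colors)
  cols[map$category + 1L]
}
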