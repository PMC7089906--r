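#' Per-category surface area of an impingement map
#'
#' Sums face areas per severity band.
#'
#' @param mesh the [trimesh] the map was computed on.
#' @param map an `impingement_map` on that mesh.
#' @return An object of class `area_report`: data frame with columns
#'   `category` (colour name) and `area_mm2`.
#' @export
area_report <- function(mesh, map) {
  stopifnot(inherits(mesh, "trimesh"), inherits(map, "impingement_map"))
  if (nrow(mesh$faces) != map$n_faces)
    stop("map face count does not match the mesh")
  k <- length(map$categories$fractions)
  areas <- vapply(seq_len(k), function(j)
    face_area(mesh, which(map$category == j)), numeric(1))
  out <- data.frame(category = map$categories$colors, area_mm2 = areas)
  attr(out, "bone") <- map$bone
  attr(out, "mode") <- map$mode
  class(out) <- c("area_report", "data.frame")
  out
}

#' Pre-to-post reduction of impinged areas
#'
#' Percentage reduction `100 * (pre - post) / pre` of each severity band's
#' surface area between a pre-operative and a post-operative analysis.
#' Bands absent pre-operatively get `NA`; negative reductions (area grew,
#' e.g. from segmentation/alignment differences) are reported with a
#' warning.  Areas, not face correspondences, are compared: the two
#' geometries generally have different tessellations.
#'
#' @param pre,post `area_report`s with identical categories.
#' @return An `area_report` with columns `category`, `pre_mm2`, `post_mm2`,
#'   `reduction_pct`.
#' @export
reduction <- function(pre, post) {
  stopifnot(inherits(pre, "area_report"), inherits(post, "area_report"))
  if (!identical(as.character(pre$category), as.character(post$category)))
    stop("pre and post reports use different categories")
  red <- ifelse(pre$area_mm2 > 0,
                100 * (pre$area_mm2 - post$area_mm2) / pre$area_mm2,
                NA_real_)
  if (any(red < 0, na.rm = TRUE))
    warning("negative reduction in band(s): ",
            paste(pre$category[which(red < 0)], collapse = ", "),
            " (post-operative area exceeds pre-operative)")
  out <- data.frame(category = pre$category, pre_mm2 = pre$area_mm2,
                    post_mm2 = post$area_mm2, reduction_pct = red)
  class(out) <- c("area_report", "data.frame")
  out
}

#' Write colour-coded meshes in one of the three representation styles
#'
#' Style `"ITBI"` writes one coloured pelvis; `"BTBI"` writes pelvis and
#' femur; `"combined"` writes pelvis (ITBI and BTBI merged, most severe
#' colour winning) and femur.
#'
#' @param model the [hip_model].
#' @param maps named list with elements `itbi` (list with `$pelvis`) and/or
#'   `btbi` (list with `$pelvis`, `$femur`) as returned by
#'   [map_impingement()]; styles only need the maps they use.
#' @param style `"ITBI"`, `"BTBI"` or `"combined"`.
#' @param out_dir output directory (created if needed).
#' @param palette colour palette, see [default_palette()].
#' @return Character vector of files written.
#' @export
render_maps <- function(model, maps, style = c("ITBI", "BTBI", "combined"),
                        out_dir = ".", palette = NULL) {
  style <- match.arg(style)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mirror <- identical(model$side, "left")
  need <- switch(style, ITBI = "itbi", BTBI = "btbi", combined = c("itbi", "btbi"))
  missing <- setdiff(need, names(maps))
  if (length(missing))
    stop("style ", style, " needs map(s): ", paste(missing, collapse = ", "))
  emit <- function(mesh, map, file) {
    if (is.null(palette))
      palette <- default_palette(map$categories$colors,
                                 map$categories$non_impinged)
    path <- file.path(out_dir, file)
    save_colored_mesh(mesh, map_face_colors(map), path, palette = palette,
                      mirror = mirror)
    path
  }
  switch(style,
         ITBI = c(emit(model$pelvis, maps$itbi$pelvis, "pelvis_itbi.ply")),
         BTBI = c(emit(model$pelvis, maps$btbi$pelvis, "pelvis_btbi.ply"),
                  emit(model$femur, maps$btbi$femur, "femur_btbi.ply")),
         combined = c(emit(model$pelvis,
                           combine_maps(maps$itbi$pelvis, maps$btbi$pelvis),
                           "pelvis_combined.ply"),
                      emit(model$femur, maps$btbi$femur,
                           "femur_combined.ply")))
}

#' Write per-band area tables to CSV
#' @param reports named list of `area_report`s (names unused; bone/mode are
#'   taken from each report's attributes).
#' @param path output CSV.
#' @export
write_areas_csv <- function(reports, path) {
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(bone = attr(r, "bone"), mode = attr(r, "mode"),
               category = r$category, area_mm2 = r$area_mm2)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
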