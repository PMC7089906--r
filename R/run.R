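#' Load a run configuration
#'
#' Reads a YAML configuration listing the four mesh files, the joint
#' geometry, side, activity definitions and sweep/category parameters.
#' Missing optional entries fall back to package defaults (the four
#' standard check activities, default sweep resolutions and the
#' red/yellow/green/blue banding).
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (nm in c("pelvis", "femur", "stem", "liner")) {
    f <- cfg$meshes[[nm]]
    if (is.null(f)) stop("config lacks meshes$", nm)
    if (!file.exists(f)) stop("mesh file not found: ", f)
  }
  if (is.null(cfg$hip_center) || is.null(cfg$femur_axis_point))
    stop("config must give hip_center and femur_axis_point")
  sw <- cfg$sweep
  cfg$sweep <- sweep_params(
    dt_pos = sw$dt_pos %||% 5, dt_alpha = sw$dt_alpha %||% 1,
    n_alpha = sw$n_alpha %||% 61, dt_con = sw$dt_con %||% 10)
  cfg$categories <- if (is.null(cfg$categories)) cca_categories()
  else cca_categories(fractions = unlist(cfg$categories$fractions),
                      colors = unlist(cfg$categories$colors))
  cfg$side <- cfg$side %||% "right"
  cfg$activities <- if (is.null(cfg$activities)) default_activities()
  else lapply(cfg$activities, function(a)
    activity(a$name,
             posture(a$initial$flexion %||% 0, a$initial$abduction %||% 0,
                     a$initial$rotation %||% 0),
             posture(a$final$flexion %||% 0, a$final$abduction %||% 0,
                     a$final$rotation %||% 0)))
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full impingement analysis
#'
#' Executes the whole pipeline on a configuration or an in-memory model:
#' per-activity clearance profiles, BTBI and ITBI mapping, the
#' infeasible-contact filter, the three rendering styles, and the CSV/JSON
#' artifacts (`cca_profile.csv`, `areas.csv`, coloured PLYs, and a machine
#' readable `manifest.json` recording all parameters).  The pipeline is
#' deterministic: identical inputs give byte-identical outputs.
#'
#' @param config a `run_config` from [load_run_config()], or `NULL` when
#'   `model` is given directly.
#' @param out_dir output directory.
#' @param model optionally a [hip_model] (overrides the config meshes).
#' @param activities,params,categories used with `model`; defaults as in
#'   [load_run_config()].
#' @return Invisibly, a list with the profiles, maps, reports and file
#'   paths.
#' @export
run_impingement <- function(config = NULL, out_dir = ".", model = NULL,
                            activities = default_activities(),
                            params = sweep_params(),
                            categories = cca_categories()) {
  if (is.null(model)) {
    stopifnot(inherits(config, "run_config"))
    mirror <- identical(config$side, "left")
    meshes <- lapply(config$meshes[c("pelvis", "femur", "stem", "liner")],
                     load_mesh, mirror = mirror)
    ctr <- as.numeric(unlist(config$hip_center))
    fap <- as.numeric(unlist(config$femur_axis_point))
    if (mirror) { ctr <- mirror_point(ctr); fap <- mirror_point(fap) }
    model <- hip_model(meshes$pelvis, meshes$femur, meshes$stem,
                       meshes$liner, ctr, fap, side = config$side)
    activities <- config$activities
    params <- config$sweep
    categories <- config$categories
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- lapply(activities, function(a) {
    message("clearance profile: ", a$name)
    compute_cca_profile(model, a, params)
  })
  message("mapping BTBI")
  btbi <- map_impingement(model, profiles, categories, params, "BTBI")
  message("mapping ITBI")
  itbi_raw <- map_impingement(model, profiles, categories, params, "ITBI")
  itbi <- itbi_raw
  itbi$pelvis <- filter_itbi(itbi_raw$pelvis, btbi$pelvis)
  maps <- list(itbi = itbi, btbi = btbi)
  files <- c(render_maps(model, maps, "ITBI", out_dir),
             render_maps(model, maps, "BTBI", out_dir),
             render_maps(model, maps, "combined", out_dir))
  write_cca_csv(profiles, file.path(out_dir, "cca_profile.csv"))
  reports <- list(
    itbi_pelvis = area_report(model$pelvis, itbi$pelvis),
    btbi_pelvis = area_report(model$pelvis, btbi$pelvis),
    btbi_femur = area_report(model$femur, btbi$femur))
  write_areas_csv(reports, file.path(out_dir, "areas.csv"))
  manifest <- list(
    package = "impingemap",
    version = as.character(utils::packageVersion("impingemap")),
    side = model$side,
    sweep = unclass(params),
    categories = list(fractions = categories$fractions,
                      colors = categories$colors),
    activities = lapply(activities, function(a)
      list(name = a$name, initial = unclass(a$initial),
           final = unclass(a$final))),
    hip_center = model$hip_center,
    femur_axis_point = model$femur_axis_point)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, profiles = profiles, maps = maps,
                 reports = reports,
                 files = c(files, file.path(out_dir, c(
                   "cca_profile.csv", "areas.csv", "manifest.json")))))
}

#' Compare two analysis runs (pre- vs post-operative)
#'
#' Reads the `areas.csv` and `manifest.json` of two completed runs,
#' verifies that activities and parameters match, and writes
#' `reduction.csv` with the per-band, per-mode percentage area reductions.
#'
#' @param pre_dir,post_dir output directories of two [run_impingement()]
#'   runs on co-registered pre-/post-operative geometry.
#' @param out output CSV path (default `reduction.csv` in `post_dir`).
#' @return The reduction table, invisibly.
#' @export
compare_runs <- function(pre_dir, post_dir,
                         out = file.path(post_dir, "reduction.csv")) {
  man_pre <- jsonlite::read_json(file.path(pre_dir, "manifest.json"))
  man_post <- jsonlite::read_json(file.path(post_dir, "manifest.json"))
  for (key in c("sweep", "categories", "activities"))
    if (!identical(man_pre[[key]], man_post[[key]]))
      stop("runs are not comparable: '", key, "' differs between manifests")
  pre <- utils::read.csv(file.path(pre_dir, "areas.csv"))
  post <- utils::read.csv(file.path(post_dir, "areas.csv"))
  key <- function(d) paste(d$bone, d$mode, d$category)
  if (!identical(sort(key(pre)), sort(key(post))))
    stop("runs are not comparable: area tables differ in shape")
  post <- post[match(key(pre), key(post)), ]
  red <- ifelse(pre$area_mm2 > 0,
                100 * (pre$area_mm2 - post$area_mm2) / pre$area_mm2,
                NA_real_)
  if (any(red < 0, na.rm = TRUE))
    warning("negative reduction(s): post-operative area exceeds ",
            "pre-operative in some band(s)")
  tab <- data.frame(bone = pre$bone, mode = pre$mode,
                    category = pre$category, pre_mm2 = pre$area_mm2,
                    post_mm2 = post$area_mm2, reduction_pct = red)
  utils::write.csv(tab, out, row.names = FALSE)
  invisible(tab)
}
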