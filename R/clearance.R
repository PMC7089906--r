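#' Conical clearance angle (CCA) at one posture
#'
#' Finds the maximum aperture of a hypothetical conical femur motion, about
#' the femoral axis at the posture, before prosthetic impingement (PI).
#' Aperture angles `alpha = 0, dt_alpha, 2 dt_alpha, ...` are swept in
#' order; for each aperture every conical position (azimuth step `dt_con`)
#' is checked for stem-liner contact and the first aperture showing PI at
#' any position is returned.  The sweep starts at `alpha = 0`, so a CCA of
#' 0 encodes "the posture itself impinges".  If no PI occurs the search
#' caps at `dt_alpha * (n_alpha - 1)`.
#'
#' @param model a [hip_model].
#' @param posture a [posture].
#' @param params a [sweep_params].
#' @return `list(cca, capped)`: the clearance angle in degrees and whether
#'   it equals the user-defined maximum.
#' @export
compute_cca <- function(model, posture, params = sweep_params()) {
  stopifnot(inherits(model, "hip_model"), inherits(params, "sweep_params"))
  ptf <- posture_transform(posture, model)
  a0 <- model$femur_axis_point - model$hip_center
  axis <- as.numeric(ptf$R %*% (a0 / sqrt(sum(a0^2))))
  cap <- params$dt_alpha * (params$n_alpha - 1L)
  if (nrow(model$stem$faces) == 0L || nrow(model$liner$faces) == 0L)
    return(list(cca = cap, capped = TRUE))
  # enumerate the aperture/azimuth sweep (aperture-major, azimuth-minor,
  # matching the early-exit loop order) and find the first crossing pose
  poses <- list()
  pose_alpha <- numeric(0)
  for (j in seq_len(params$n_alpha)) {
    alpha <- params$dt_alpha * (j - 1L)
    cones <- conical_positions(axis, alpha, params$dt_con, model$hip_center)
    if (alpha == 0) cones <- cones[1L]   # degenerate cone: all identical
    for (tf in cones) {
      poses[[length(poses) + 1L]] <- tf_compose(tf, ptf)
      pose_alpha <- c(pose_alpha, alpha)
    }
  }
  R_all <- do.call(rbind, lapply(poses, `[[`, "R"))
  T_all <- do.call(rbind, lapply(poses, `[[`, "t"))
  hit <- first_crossing_pose_cpp(model$stem$vertices,
                                 model$stem$edges - 1L,
                                 model$stem$faces - 1L,
                                 model$liner$vertices,
                                 model$liner$edges - 1L,
                                 model$liner$faces - 1L, R_all, T_all)
  cca <- if (hit == 0L) cap else pose_alpha[hit]
  list(cca = cca, capped = (cca == cap))
}

#' Per-posture CCA profile of an activity
#'
#' Applies [compute_cca()] to every posture of the discretised activity, in
#' order.  The profile is both the clearance summary (box-plot data) and
#' the input to the impingement mapping step.
#'
#' @inheritParams compute_cca
#' @param activity an [activity].
#' @return An object of class `cca_profile`: a data frame with columns
#'   `posture` (index), `flexion`, `abduction`, `rotation`, `cca_deg`,
#'   `capped`, with the activity name as attribute `"activity"`.
#' @export
compute_cca_profile <- function(model, activity, params = sweep_params()) {
  stopifnot(inherits(activity, "activity"))
  postures <- discretize_activity(activity, params$dt_pos)
  rows <- lapply(seq_along(postures), function(i) {
    p <- postures[[i]]
    r <- compute_cca(model, p, params)
    data.frame(posture = i, flexion = p$flexion, abduction = p$abduction,
               rotation = p$rotation, cca_deg = r$cca, capped = r$capped)
  })
  out <- do.call(rbind, rows)
  attr(out, "activity") <- activity$name
  attr(out, "postures") <- postures
  class(out) <- c("cca_profile", "data.frame")
  out
}

#' @export
print.cca_profile <- function(x, ...) {
  cat("CCA profile for activity '", attr(x, "activity"), "' (",
      nrow(x), " postures)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cca_profile <- function(object, ...) {
  cat("Activity:", attr(object, "activity"), "\n")
  cat(sprintf("CCA (deg): min %.1f, median %.1f, max %.1f; %d/%d capped\n",
              min(object$cca_deg), stats::median(object$cca_deg),
              max(object$cca_deg), sum(object$capped), nrow(object)))
  if (any(object$cca_deg == 0))
    cat("warning: zero CCA at posture(s)",
        paste(object$posture[object$cca_deg == 0], collapse = ", "),
        "- the motion itself causes prosthetic impingement\n")
  invisible(object)
}

#' Box plot of per-posture clearance angles
#' @param x one `cca_profile` or a list of them.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.cca_profile <- function(x, ...) {
  graphics::boxplot(list(x$cca_deg), names = attr(x, "activity"),
                    ylab = "conical clearance angle (deg)", ...)
  invisible(x)
}

#' Write CCA profiles to CSV
#'
#' One row per posture: activity, posture index, the three joint angles,
#' `cca_deg` and `capped`.
#' @param profiles list of `cca_profile`s (or a single one).
#' @param path output CSV file.
#' @export
write_cca_csv <- function(profiles, path) {
  if (inherits(profiles, "cca_profile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, function(p) {
    cbind(activity = attr(p, "activity"), as.data.frame(p))
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
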