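#' Hip posture
#'
#' Joint angles in degrees.  Conventions (right hip, pelvis-fixed anatomical
#' frame: x antero-posterior pointing anterior, y medio-lateral pointing
#' lateral, z superior-inferior pointing superior):
#' flexion positive = femur tilts anteriorly (negative = extension);
#' abduction positive = femur tilts laterally (negative = adduction);
#' rotation positive = internal, negative = external.
#'
#' @param flexion,abduction,rotation angles in degrees, each within
#'   \[-90, 150\] as a sanity bound.
#' @export
posture <- function(flexion = 0, abduction = 0, rotation = 0) {
  ang <- c(unname(flexion)[1], unname(abduction)[1], unname(rotation)[1])
  if (any(!is.finite(ang))) stop("posture angles must be finite")
  if (any(ang < -90 | ang > 150))
    stop("posture angles outside the [-90, 150] degree sanity range")
  structure(list(flexion = ang[1], abduction = ang[2], rotation = ang[3]),
            class = "posture")
}

#' @export
print.posture <- function(x, ...) {
  cat(sprintf("posture: flexion %g, abduction %g, rotation %g (deg)\n",
              x$flexion, x$abduction, x$rotation))
  invisible(x)
}

#' Hip activity: a motion from an initial to a final posture
#' @param name activity label.
#' @param initial,final [posture]s; must differ in at least one component.
#' @export
activity <- function(name, initial, final) {
  stopifnot(inherits(initial, "posture"), inherits(final, "posture"))
  if (all(unlist(initial) == unlist(final)))
    stop("zero-length activity: initial and final postures are identical")
  structure(list(name = name, initial = initial, final = final),
            class = "activity")
}

#' The four standard check activities
#'
#' Extension to 10 deg, flexion to 90 deg, external rotation to 25 deg at
#' 10 deg extension, and internal rotation to 35 deg at 90 deg flexion --
#' the motions typically tested intra-operatively for impingement.
#' Extension is modelled as negative flexion, external rotation as negative
#' rotation.
#' @return List of [activity] objects.
#' @export
default_activities <- function() {
  list(
    activity("Extn", posture(0, 0, 0), posture(-10, 0, 0)),
    activity("Flex", posture(0, 0, 0), posture(90, 0, 0)),
    activity("ER_Ext", posture(-10, 0, 0), posture(-10, 0, -25)),
    activity("IR_Flex", posture(90, 0, 0), posture(90, 0, 35))
  )
}

#' Sweep resolutions for the clearance and impingement searches
#'
#' @param dt_pos posture discretisation step (deg, default 5).
#' @param dt_alpha aperture-angle step of the clearance search (deg,
#'   default 1).
#' @param n_alpha number of aperture steps; the clearance search caps at
#'   `dt_alpha * (n_alpha - 1)` degrees (default 61, i.e. a 60 deg cap).
#' @param dt_con azimuthal step of the conical motion (deg, default 10);
#'   must divide 360 evenly.
#' @export
sweep_params <- function(dt_pos = 5, dt_alpha = 1, n_alpha = 61,
                         dt_con = 10) {
  if (dt_pos <= 0 || dt_alpha <= 0 || dt_con <= 0)
    stop("all sweep resolutions must be > 0")
  if (n_alpha < 2) stop("n_alpha must be >= 2")
  if (abs(360 / dt_con - round(360 / dt_con)) > 1e-9)
    stop("dt_con must divide 360 evenly")
  structure(list(dt_pos = dt_pos, dt_alpha = dt_alpha,
                 n_alpha = as.integer(n_alpha), dt_con = dt_con),
            class = "sweep_params")
}

#' Hip model: bone and implant meshes in one common frame
#'
#' All meshes must be co-registered, with the implants at their planned
#' pose.  `hip_center` is the centre of rotation of the articulation;
#' `femur_axis_point` is a distal point defining the neutral femoral axis
#' (the line hip_center -> femur_axis_point).
#'
#' @param pelvis,femur,stem,liner [trimesh]es (mm).
#' @param hip_center,femur_axis_point length-3 points (mm), distinct.
#' @param side `"right"` or `"left"`.  Left models should be mirrored to the
#'   right-hand convention before analysis (see [mirror_mesh()]).
#' @export
hip_model <- function(pelvis, femur, stem, liner, hip_center,
                      femur_axis_point, side = "right") {
  for (m in list(pelvis, femur, stem, liner))
    stopifnot(inherits(m, "trimesh"))
  hip_center <- as.numeric(hip_center)
  femur_axis_point <- as.numeric(femur_axis_point)
  stopifnot(length(hip_center) == 3L, length(femur_axis_point) == 3L)
  if (sqrt(sum((hip_center - femur_axis_point)^2)) < 1e-9)
    stop("hip_center and femur_axis_point must be distinct")
  side <- match.arg(side, c("right", "left"))
  structure(list(pelvis = pelvis, femur = femur, stem = stem, liner = liner,
                 hip_center = hip_center,
                 femur_axis_point = femur_axis_point, side = side),
            class = "hip_model")
}

#' @export
print.hip_model <- function(x, ...) {
  cat("hip_model (", x$side, " side)\n", sep = "")
  for (nm in c("pelvis", "femur", "stem", "liner"))
    cat(sprintf("  %-6s %6d faces\n", nm, nrow(x[[nm]]$faces)))
  cat("  hip centre:", paste(signif(x$hip_center, 4), collapse = ", "),
      "mm\n")
  invisible(x)
}

## ---- rigid transforms -----------------------------------------------------

#' Rigid transforms
#'
#' A rigid transform is stored as a rotation matrix `R` and translation `t`;
#' it maps a point p to `R p + t`.  `tf_rotation()` builds the rotation by
#' `angle_deg` about the axis direction `axis` through the point `center`.
#'
#' @param axis length-3 direction (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @param center point the rotation is about (default origin).
#' @return An object of class `rigid_transform`.
#' @export
tf_rotation <- function(axis, angle_deg, center = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) stop("rotation axis must be non-zero")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  tf_from_R(R, center)
}

#' @rdname tf_rotation
#' @param R 3 x 3 rotation matrix.
#' @export
tf_from_R <- function(R, center = c(0, 0, 0)) {
  center <- as.numeric(center)
  structure(list(R = R, t = as.numeric(center - R %*% center)),
            class = "rigid_transform")
}

#' @rdname tf_rotation
#' @export
tf_identity <- function() {
  structure(list(R = diag(3), t = c(0, 0, 0)), class = "rigid_transform")
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b `rigid_transform`s.
#' @export
tf_compose <- function(a, b) {
  structure(list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t) + a$t),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @export
tf_inverse <- function(tf) {
  Rt <- t(tf$R)
  structure(list(R = Rt, t = as.numeric(-Rt %*% tf$t)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#' @param tf a `rigid_transform`.
#' @param x length-3 point, n x 3 matrix, or [trimesh].
#' @export
tf_apply <- function(tf, x) {
  if (inherits(x, "trimesh")) {
    x$vertices <- tf_apply(tf, x$vertices)
    return(x)
  }
  if (is.matrix(x)) return(sweep(x %*% t(tf$R), 2L, tf$t, "+"))
  as.numeric(tf$R %*% as.numeric(x)) + tf$t
}

## ---- activity discretisation ---------------------------------------------

#' Discretise an activity into postures
#'
#' Simultaneous linear interpolation from the initial to the final posture
#' such that the largest-moving angle component changes by `dt_pos` per
#' step.  Both endpoints are always included; when the range is not an
#' integer multiple of `dt_pos` the final posture is appended as the last
#' element.  E.g. flexion 0 -> 90 deg at a 30 deg step gives the four
#' postures 0, 30, 60, 90.
#'
#' @param activity an [activity].
#' @param dt_pos posture step in degrees (> 0).
#' @return Ordered list of [posture]s.
#' @export
discretize_activity <- function(activity, dt_pos) {
  stopifnot(inherits(activity, "activity"), dt_pos > 0)
  a0 <- unlist(activity$initial)
  a1 <- unlist(activity$final)
  rng <- max(abs(a1 - a0))
  k <- floor(rng / dt_pos + 1e-9)
  fr <- seq(0, k) * dt_pos / rng
  if (k * dt_pos < rng - 1e-9 * max(1, rng)) fr <- c(fr, 1)
  lapply(fr, function(f) {
    ang <- a0 + f * (a1 - a0)
    posture(ang[1], ang[2], ang[3])
  })
}

## ---- posture and conical-motion transforms --------------------------------

#' Rigid transform realising a posture
#'
#' Pure rotation about the hip centre (ball joint, no translation), composed
#' in the fixed order flexion (about the pelvis medio-lateral y axis), then
#' abduction (about the antero-posterior x axis), then axial rotation about
#' the current femoral axis.  The zero posture gives the identity.
#'
#' @param posture a [posture].
#' @param model a [hip_model] (supplies hip centre and neutral femoral
#'   axis).
#' @return A `rigid_transform`.
#' @export
posture_transform <- function(posture, model) {
  stopifnot(inherits(posture, "posture"), inherits(model, "hip_model"))
  ctr <- model$hip_center
  a0 <- model$femur_axis_point - ctr
  a0 <- a0 / sqrt(sum(a0^2))
  # flexion about y: positive tilts the distal femur (-z-ish) anteriorly (+x)
  Rf <- tf_rotation(c(0, 1, 0), -posture$flexion, ctr)
  # abduction about x: positive tilts the distal femur laterally (+y)
  Ra <- tf_rotation(c(1, 0, 0), posture$abduction, ctr)
  Rfa <- tf_compose(Ra, Rf)
  axis <- as.numeric(Rfa$R %*% a0)
  # internal rotation positive about the distal-pointing femoral axis
  Rr <- tf_rotation(axis, -posture$rotation, ctr)
  tf_compose(Rr, Rfa)
}

#' Positions of a conical femur motion
#'
#' Constructs the `360 / dt_con` rigid transforms of the hypothetical
#' conical motion: transform k tilts the femur about the hip centre so its
#' axis makes the aperture angle `alpha` with `posture_axis`, at azimuth
#' `k * dt_con` about that axis.  `alpha = 0` gives identities.  Azimuth 0
#' is the projection of the +x axis onto the plane normal to `posture_axis`
#' (the +y axis when the posture axis is near x).
#'
#' @param posture_axis unit 3-vector, the femoral axis at the posture.
#' @param alpha aperture angle in degrees (>= 0).
#' @param dt_con azimuthal step (deg); must divide 360.
#' @param hip_center rotation centre.
#' @return List of `rigid_transform`s of length `360 / dt_con`.
#' @export
conical_positions <- function(posture_axis, alpha, dt_con, hip_center) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (abs(360 / dt_con - round(360 / dt_con)) > 1e-9)
    stop("dt_con must divide 360 evenly")
  n <- posture_axis / sqrt(sum(posture_axis^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  nk <- as.integer(round(360 / dt_con))
  lapply(seq_len(nk) - 1L, function(k) {
    if (alpha == 0) return(tf_identity())
    phi <- (k * dt_con) * pi / 180
    w <- cos(phi) * u + sin(phi) * v   # tilt direction at this azimuth
    tf_rotation(.cross3(n, w), alpha, hip_center)
  })
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
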