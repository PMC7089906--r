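test_that("activity discretisation follows the stepping rule", {
  flex <- activity("Flex", posture(0, 0, 0), posture(90, 0, 0))
  p <- discretize_activity(flex, 30)
  expect_length(p, 4L)
  expect_equal(vapply(p, `[[`, numeric(1), "flexion"), c(0, 30, 60, 90))

  ir <- activity("IR_Flex", posture(90, 0, 0), posture(90, 0, 35))
  p <- discretize_activity(ir, 5)
  expect_length(p, 8L)
  expect_equal(vapply(p, `[[`, numeric(1), "rotation"), seq(0, 35, by = 5))
  expect_true(all(vapply(p, `[[`, numeric(1), "flexion") == 90))

  # range not a multiple of the step: both endpoints kept
  short <- activity("s", posture(0, 0, 0), posture(10, 0, 0))
  p <- discretize_activity(short, 25)
  expect_length(p, 2L)
  expect_equal(vapply(p, `[[`, numeric(1), "flexion"), c(0, 10))
})

test_that("discretisation is monotone with unique endpoints", {
  set.seed(42)
  for (i in 1:20) {
    a0 <- stats::runif(3, -40, 40)
    a1 <- a0 + stats::runif(3, -50, 50)
    if (max(abs(a1 - a0)) < 1) a1[1] <- a0[1] + 10
    act <- activity("r", posture(a0[1], a0[2], a0[3]),
                    posture(a1[1], a1[2], a1[3]))
    p <- discretize_activity(act, stats::runif(1, 2, 20))
    ang <- t(vapply(p, unlist, numeric(3)))
    for (j in 1:3) {
      d <- diff(ang[, j])
      expect_true(all(d >= -1e-9) || all(d <= 1e-9))
    }
    expect_equal(ang[1, ], a0, ignore_attr = TRUE)
    expect_equal(ang[nrow(ang), ], a1, ignore_attr = TRUE)
    expect_equal(nrow(unique(round(ang, 9))), nrow(ang))
  }
  expect_error(activity("z", posture(1, 2, 3), posture(1, 2, 3)),
               "zero-length")
})

make_minimal_model <- function() {
  s <- sphere_mesh(1, edge = 0.6)
  hip_model(s, s, s, s, hip_center = c(10, 20, 30),
            femur_axis_point = c(10, 20, -70))
}

test_that("posture transforms are proper rotations about the hip centre", {
  model <- make_minimal_model()
  id <- posture_transform(posture(0, 0, 0), model)
  expect_equal(id$R, diag(3))
  expect_equal(id$t, c(0, 0, 0))

  set.seed(3)
  for (i in 1:20) {
    p <- posture(stats::runif(1, -90, 120), stats::runif(1, -40, 45),
                 stats::runif(1, -40, 40))
    tf <- posture_transform(p, model)
    expect_equal(t(tf$R) %*% tf$R, diag(3), tolerance = 1e-12)
    expect_equal(det(tf$R), 1, tolerance = 1e-12)
    expect_equal(tf_apply(tf, model$hip_center), model$hip_center,
                 tolerance = 1e-9)
  }
})

test_that("pure flexion rotates the femoral axis in the sagittal plane", {
  model <- make_minimal_model()
  tf <- posture_transform(posture(90, 0, 0), model)
  img <- tf_apply(tf, model$femur_axis_point)
  # rotation about the medio-lateral (y) axis: y-coordinate unchanged,
  # image orthogonal to the start, anterior (+x) at 90 degrees of flexion
  expect_equal(img[2], model$femur_axis_point[2])
  v0 <- model$femur_axis_point - model$hip_center
  v1 <- img - model$hip_center
  expect_equal(sum(v0 * v1), 0, tolerance = 1e-9)
  expect_gt(v1[1], 0)
})

test_that("conical positions tilt the axis by alpha at uniform azimuths", {
  expect_length(conical_positions(c(0, 0, -1), 20, 45, c(0, 0, 0)), 8L)
  expect_error(conical_positions(c(0, 0, -1), 20, 77, c(0, 0, 0)),
               "divide 360")

  axis <- c(0, 0, -1)
  for (tf in conical_positions(axis, 0, 30, c(0, 0, 0)))
    expect_equal(tf_apply(tf, axis), axis, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:15) {
    n <- rand_unit()
    alpha <- stats::runif(1, 0.5, 80)
    ctr <- stats::rnorm(3, sd = 20)
    tfs <- conical_positions(n, alpha, 30, ctr)
    expect_length(tfs, 12L)
    tilted <- lapply(tfs, function(tf) as.numeric(tf$R %*% n))
    for (tn in tilted) {
      ang <- acos(pmin(1, pmax(-1, sum(tn * n)))) * 180 / pi
      expect_equal(ang, alpha, tolerance = 1e-9 * 180 / pi)
    }
    for (tf in tfs)
      expect_equal(tf_apply(tf, ctr), ctr, tolerance = 1e-9)
    # uniform azimuth spacing: consecutive tilted axes subtend equal angles
    gaps <- vapply(seq_along(tilted), function(k) {
      nk <- tilted[[k]]
      nk1 <- tilted[[if (k == length(tilted)) 1L else k + 1L]]
      acos(pmin(1, pmax(-1, sum(nk * nk1))))
    }, numeric(1))
    expect_lt(diff(range(gaps)), 1e-9)
  }
})

test_that("posture plus conical tilt is a rigid motion of the mesh", {
  model <- make_minimal_model()
  mesh <- sphere_mesh(2, center = c(11, 21, 28), edge = 1.2)
  p <- posture(35, 10, -15)
  ptf <- posture_transform(p, model)
  axis <- as.numeric(ptf$R %*% c(0, 0, -1))
  tilt <- conical_positions(axis, 17, 90, model$hip_center)[[2]]
  pose <- tf_compose(tilt, ptf)
  moved <- tf_apply(pose, mesh)
  set.seed(8)
  i <- sample(nrow(mesh$vertices), 40)
  j <- sample(nrow(mesh$vertices), 40)
  d0 <- sqrt(rowSums((mesh$vertices[i, ] - mesh$vertices[j, ])^2))
  d1 <- sqrt(rowSums((moved$vertices[i, ] - moved$vertices[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("sweep parameter invariants are enforced", {
  expect_error(sweep_params(dt_con = 7), "divide 360")
  expect_error(sweep_params(dt_alpha = 0), "> 0")
  expect_error(sweep_params(n_alpha = 1), "n_alpha")
  p <- sweep_params()
  expect_equal(p$dt_pos, 5)
  expect_equal(p$dt_alpha, 1)
  expect_equal(p$dt_con, 10)
})
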