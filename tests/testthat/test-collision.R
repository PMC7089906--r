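test_that("ray_triangle matches the axis-aligned closed form", {
  hit <- ray_triangle(c(0.2, 0.2, -1), c(0, 0, 1),
                      c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(hit$t, 1)
  expect_equal(hit$u, 0.2)
  expect_equal(hit$v, 0.2)
  # parallel ray misses
  expect_null(ray_triangle(c(0.2, 0.2, -1), c(1, 0, 0),
                           c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_error(ray_triangle(c(0, 0, 0), c(0, 0, 0),
                            c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               "non-zero")
})

test_that("ray_triangle agrees with a plane/barycentric oracle", {
  set.seed(101)
  n_agree <- 0L
  for (i in 1:1000) {
    rt <- rand_ray_triangle()
    mt <- ray_triangle(rt$o, rt$d, rt$tri[1, ], rt$tri[2, ], rt$tri[3, ])
    or <- plane_bary_hit(rt$o, rt$d, rt$tri[1, ], rt$tri[2, ], rt$tri[3, ])
    expect_equal(is.null(mt), is.null(or))
    if (!is.null(mt)) {
      expect_lt(abs(mt$t - or$t), 1e-9)
      n_agree <- n_agree + 1L
    }
  }
  expect_gt(n_agree, 50L)  # the sample must actually exercise hits
})

test_that("disjoint and overlapping spheres are classified correctly", {
  s1 <- sphere_mesh(1, c(0, 0, 0), edge = 0.25)
  s2 <- sphere_mesh(1, c(3, 0.1, 0.05), edge = 0.25)
  expect_false(mesh_intersect(s1, s2)$intersects)

  s3 <- sphere_mesh(1, c(1, 0.013, 0.007), edge = 0.25)
  r <- mesh_intersect(s1, s3)
  expect_true(r$intersects)
  # intersection circle of two unit spheres ~1 mm apart: radius ~ sqrt(3)/2
  ctr <- c(1, 0.013, 0.007) / 2
  ax <- c(1, 0.013, 0.007) / sqrt(sum(c(1, 0.013, 0.007)^2))
  rel <- sweep(r$boundary_points, 2, ctr)
  axial <- as.numeric(rel %*% ax)
  radial <- sqrt(rowSums((rel - outer(axial, ax))^2))
  expect_true(all(abs(radial - sqrt(3) / 2) < 0.02))
  # boundary points lie on both faceted surfaces
  for (k in seq_len(min(25, nrow(r$boundary_points)))) {
    p <- r$boundary_points[k, ]
    expect_lt(min_dist_to_faces(p, s1, r$crossed_faces_a), 1e-6)
    expect_lt(min_dist_to_faces(p, s3, r$crossed_faces_b), 1e-6)
  }
})

test_that("intersection is symmetric and rigidly invariant", {
  set.seed(17)
  s1 <- sphere_mesh(1.2, c(0, 0, 0), edge = 0.3)
  s2 <- sphere_mesh(0.9, c(1.4, 0.2, -0.1), edge = 0.3)
  tfa <- rand_rotation(center = c(0.3, 0, 0))
  expect_equal(mesh_intersect(s1, s2, transform_a = tfa)$intersects,
               mesh_intersect(s2, s1, transform_a = tf_inverse(tfa))$intersects)

  r0 <- mesh_intersect(s1, s2)
  g <- rand_rotation(center = c(5, -3, 2))
  r1 <- mesh_intersect(tf_apply(g, s1), tf_apply(g, s2))
  expect_equal(sort(r1$crossed_faces_b), sort(r0$crossed_faces_b))
  p0 <- tf_apply(g, r0$boundary_points)
  ord <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  expect_equal(ord(r1$boundary_points), ord(p0), tolerance = 1e-8)
})

test_that("grid broad phase equals exhaustive testing", {
  set.seed(23)
  for (i in 1:4) {
    c2 <- c(1.1, 0, 0) + stats::rnorm(3, sd = 0.15)
    s1 <- tf_apply(rand_rotation(), sphere_mesh(1, c(0, 0, 0), edge = 0.35))
    s2 <- tf_apply(rand_rotation(c2),
                   sphere_mesh(stats::runif(1, 0.7, 1.2), c2, edge = 0.35))
    rg <- mesh_intersect(s1, s2, method = "grid")
    re <- mesh_intersect(s1, s2, method = "exhaustive")
    expect_identical(rg$intersects, re$intersects)
    expect_identical(rg$crossed_faces_a, re$crossed_faces_a)
    expect_identical(rg$crossed_faces_b, re$crossed_faces_b)
    expect_identical(rg$crossed_vertices_a, re$crossed_vertices_a)
    expect_identical(rg$crossed_vertices_b, re$crossed_vertices_b)
    ord <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
    expect_equal(ord(rg$boundary_points), ord(re$boundary_points),
                 tolerance = 1e-12)
  }
})

test_that("prosthetic impingement turns on past the rim-contact tilt", {
  spec <- fixture_spec(mesh_edge_length = 2.5)
  model <- make_hip_fixture(spec)
  tstar <- analytic_rim_contact(spec)
  expect_false(check_pi(model$stem, model$liner, tf_identity()))
  tilt <- function(t) tf_rotation(c(0, 1, 0), -t, c(0, 0, 0))
  expect_true(check_pi(model$stem, model$liner, tilt(tstar + 2)))
  # monotone along one azimuth: once in contact, stays in contact
  state <- vapply(seq(0, 55, by = 2.5), function(t)
    check_pi(model$stem, model$liner, tilt(t)), logical(1))
  expect_true(all(diff(state) >= 0))
  # empty liner never impinges
  empty <- trimesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_false(check_pi(model$stem, empty, tilt(50)))
})

test_that("ray parity containment classifies sphere points", {
  s <- sphere_mesh(2, c(1, 1, 1), edge = 0.5)
  expect_true(point_in_mesh(c(1, 1, 1), s))
  expect_true(point_in_mesh(c(2.4, 1, 1), s))
  expect_false(point_in_mesh(c(4, 1, 1), s))
  tf <- tf_rotation(c(0, 0, 1), 90, c(0, 0, 0))
  expect_true(point_in_mesh(tf_apply(tf, c(2.4, 1, 1)), s, transform = tf))
})
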