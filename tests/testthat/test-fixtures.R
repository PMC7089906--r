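test_that("fixtures are valid, closed, deterministic and PI-free", {
  spec <- fixture_spec(mesh_edge_length = 3)
  m1 <- make_hip_fixture(spec)
  m2 <- make_hip_fixture(spec)
  for (nm in c("pelvis", "femur", "stem", "liner")) {
    expect_true(is_closed(m1[[nm]]))
    expect_identical(m1[[nm]]$vertices, m2[[nm]]$vertices)
    expect_identical(m1[[nm]]$faces, m2[[nm]]$faces)
  }
  expect_false(check_pi(m1$stem, m1$liner, tf_identity()))

  bumped <- bump_spec_for_reach(25, edge = 3)
  mb <- make_hip_fixture(bumped)
  expect_true(is_closed(mb$pelvis))
  expect_false(mesh_intersect(mb$femur, mb$pelvis,
                              transform_a = tf_identity(),
                              any_hit = TRUE)$intersects)
})

test_that("fixture resolution scales vertex counts like 1/edge^2", {
  n1 <- nrow(make_hip_fixture(fixture_spec(mesh_edge_length = 3))$liner$vertices)
  n2 <- nrow(make_hip_fixture(fixture_spec(mesh_edge_length = 1.5))$liner$vertices)
  expect_gt(n2 / n1, 3)
  expect_lt(n2 / n1, 6)
})

test_that("fixture spec invariants are enforced", {
  expect_error(fixture_spec(neck_radius = 17), "neck_radius < head_radius")
  expect_error(fixture_spec(rim_opening_half_angle = 95), "rim_opening")
  expect_error(fixture_spec(plate_distance = 30), "swept reach")
})

test_that("rim-contact formula limits and monotonicity hold", {
  # line-against-rim limit: the angle tends to the opening half-angle
  thin <- fixture_spec(neck_radius = 0.05, mesh_edge_length = 3)
  expect_equal(analytic_rim_contact(thin), thin$rim_opening_half_angle,
               tolerance = 0.2)
  # strictly decreasing in the neck radius
  angles <- vapply(c(3, 5, 7, 9), function(rn)
    analytic_rim_contact(fixture_spec(neck_radius = rn, head_radius = 12,
                                      mesh_edge_length = 3)),
    numeric(1))
  expect_true(all(diff(angles) < 0))
  # azimuth-independent for this axisymmetric fixture
  spec <- fixture_spec(mesh_edge_length = 3)
  expect_equal(analytic_rim_contact(spec, 0),
               analytic_rim_contact(spec, 135))
  expect_error(analytic_rim_contact(fixture_spec(
    rim_opening_half_angle = 15, neck_radius = 6, mesh_edge_length = 3)),
    "impossible")
})

test_that("rim-contact oracle is validated by a brute-force pose sweep", {
  for (beta in c(50, 60)) {
    spec <- fixture_spec(rim_opening_half_angle = beta,
                         mesh_edge_length = 2.5)
    model <- make_hip_fixture(spec)
    tstar <- analytic_rim_contact(spec)
    swept <- brute_first_crossing_tilt(model$stem, model$liner,
                                       seq(0, 60, by = 0.25))
    expect_lt(abs(swept - tstar), 0.25 + rim_mesh_term_deg(spec))
  }
})

test_that("bump-reach oracle is validated by a brute-force pose sweep", {
  for (reach in c(12, 27)) {
    spec <- bump_spec_for_reach(reach, edge = 2)
    expect_equal(analytic_bump_reach(spec), reach, tolerance = 1e-9)
    model <- make_hip_fixture(spec)
    swept <- brute_first_crossing_tilt(model$femur, model$pelvis,
                                       seq(0, 40, by = 0.25))
    expect_lt(abs(swept - reach), 1.0)  # bump + shaft faceting allowance
  }
  # a bump at half the rim-contact tilt sits mid-path by construction
  spec <- fixture_spec(mesh_edge_length = 2.5)
  half <- bump_spec_for_reach(analytic_rim_contact(spec) / 2, edge = 2.5)
  expect_equal(analytic_bump_reach(half) / analytic_rim_contact(spec), 0.5,
               tolerance = 1e-9)
})

test_that("unreachable bumps are flagged", {
  # behind the plate: pointing away from the swept cone
  spec <- fixture_spec(mesh_edge_length = 3, shaft_end = 57,
                       plate_distance = 60,
                       bump = list(direction = c(0, 0, 1), height = 10,
                                   radius = 5))
  expect_identical(analytic_bump_reach(spec), Inf)
  # axially out of the shaft span: contact point past the shaft tip
  near <- fixture_spec(mesh_edge_length = 3, shaft_start = 20,
                       shaft_end = 30, plate_distance = 60,
                       bump = list(direction = c(1, 0, -1), height = 10,
                                   radius = 2))
  expect_identical(analytic_bump_reach(near), Inf)
  expect_error(analytic_bump_reach(fixture_spec(mesh_edge_length = 3)),
               "no bump")
})

test_that("fixture sets round-trip through STL and the run config", {
  dir <- tempfile()
  spec <- fixture_spec(mesh_edge_length = 3)
  cfg_path <- write_fixture_set(spec, dir)
  expect_true(file.exists(cfg_path))
  cfg <- load_run_config(cfg_path)
  expect_s3_class(cfg, "run_config")
  orig <- make_hip_fixture(spec)
  for (nm in c("pelvis", "femur", "stem", "liner")) {
    m <- load_mesh(cfg$meshes[[nm]])
    expect_equal(nrow(m$faces), nrow(orig[[nm]]$faces))
    expect_equal(face_area(m), face_area(orig[[nm]]), tolerance = 1e-5)
  }
})
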