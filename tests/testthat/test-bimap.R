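test_that("category thresholds are the clearance fractions", {
  expect_equal(categorize(20), c(5, 10, 15, 20))
  expect_equal(categorize(0), c(0, 0, 0, 0))
  set.seed(2)
  for (cca in stats::runif(5, 1, 60))
    expect_true(all(diff(categorize(cca)) > 0))
  expect_error(categorize(-1), ">= 0")
  expect_error(cca_categories(fractions = c(0.5, 0.25),
                              colors = c("a", "b")), "strictly increasing")
})

test_that("region growing fills an unmarked closed surface as one cluster", {
  s <- sphere_mesh(2, edge = 0.6)
  cl <- region_grow(s, integer(0))
  expect_length(cl, 1L)
  expect_equal(cl[[1]], seq_len(nrow(s$faces)))
  expect_length(attr(cl, "unassigned"), 0L)
})

test_that("an equatorial crossing splits a sphere into two caps", {
  s <- sphere_mesh(2, edge = 0.5)
  zs <- sort(unique(round(s$vertices[, 3], 9)))
  band <- zs[which.min(abs(zs))]
  marked <- which(abs(s$vertices[, 3] - band) < 1e-6)
  cl <- region_grow(s, marked)
  expect_length(cl, 2L)
  # every cluster lies strictly on one side of the marked ring
  for (c in cl) {
    zc <- s$vertices[s$faces[c, ], 3]
    expect_true(all(zc > band - 1e-9) || all(zc < band + 1e-9))
  }
})

test_that("region growing equals BFS connected components of seed faces", {
  set.seed(31)
  for (i in 1:20) {
    s <- sphere_mesh(1, edge = 0.45)
    marked <- which(stats::runif(nrow(s$vertices)) < 0.15)
    got <- clusters_as_sets(region_grow(s, marked))
    want <- clusters_as_sets(rga_oracle(s, marked))
    expect_identical(got, want)
  }
})

test_that("impinged clusters match analytic sphere containment", {
  s1 <- sphere_mesh(1, c(0, 0, 0), edge = 0.15)
  s2 <- sphere_mesh(1, c(1, 0.01, 0.004), edge = 0.15)
  r <- mesh_intersect(s1, s2)
  cl <- region_grow(s2, r$crossed_vertices_b)
  imp <- select_impinged(cl, s2, s1)
  ctr <- (s2$vertices[s2$faces[, 1], ] + s2$vertices[s2$faces[, 2], ] +
            s2$vertices[s2$faces[, 3], ]) / 3
  inside <- which(sqrt(rowSums(ctr^2)) < 1)
  # impinged = analytically-contained faces, up to boundary straddlers
  expect_true(all(imp %in% inside))
  expect_true(all(setdiff(inside, imp) %in% attr(cl, "unassigned")))
  expect_error(select_impinged(region_grow(s2, integer(0)), s2, s1),
               "no crossing")
})

test_that("cluster selection is stable under face-order permutation", {
  s1 <- sphere_mesh(1, c(0, 0, 0), edge = 0.3)
  s2 <- sphere_mesh(1, c(1.1, 0.05, 0), edge = 0.3)
  r <- mesh_intersect(s1, s2)
  imp <- select_impinged(region_grow(s2, r$crossed_vertices_b), s2, s1)
  set.seed(13)
  perm <- sample(nrow(s2$faces))
  s2p <- trimesh(s2$vertices, s2$faces[perm, ], weld_tolerance = 0)
  rp <- mesh_intersect(s1, s2p)
  expect_identical(sort(perm[rp$crossed_faces_b]), r$crossed_faces_b)
  impp <- select_impinged(region_grow(s2p, rp$crossed_vertices_b), s2p, s1)
  expect_identical(sort(perm[impp]), imp)
})

hold_activity <- function() activity("hold", posture(0, 0, 0),
                                     posture(0.01, 0, 0))

map_params <- sweep_params(dt_pos = 5, dt_alpha = 1, n_alpha = 61,
                           dt_con = 45)

test_that("a bump reachable only near the clearance limit is blue only", {
  spec <- bump_spec_for_reach(31, edge = 2.5)
  model <- make_hip_fixture(spec)
  prof <- compute_cca_profile(model, hold_activity(), map_params)
  expect_true(all(prof$cca_deg == 36))  # grid ceil of the 35.53 deg contact
  bt <- map_impingement(model, prof, cca_categories(), map_params, "BTBI")
  flagged <- which(bt$pelvis$category > 0L)
  expect_gt(length(flagged), 0L)
  expect_true(all(bt$pelvis$category[flagged] == 4L))
  expect_gt(sum(bt$femur$category == 4L), 0L)
  # provenance names the activity and posture that flagged each face
  expect_true(all(bt$pelvis$provenance$activity == "hold"))
  expect_setequal(unique(bt$pelvis$provenance$face), flagged)
})

test_that("a bump contacted by the posture itself is red", {
  spec <- bump_spec_for_reach(-2, edge = 2.5)
  model <- make_hip_fixture(spec)
  prof <- compute_cca_profile(model, hold_activity(), map_params)
  bt <- map_impingement(model, prof, cca_categories(), map_params, "BTBI")
  # faces crossing at the unswept posture carry the most severe colour
  r0 <- mesh_intersect(model$femur, model$pelvis,
                       transform_a = posture_transform(posture(0, 0, 0),
                                                       model))
  expect_true(r0$intersects)
  expect_true(all(bt$pelvis$category[r0$crossed_faces_b] == 1L))
  expect_gt(face_area(model$pelvis, which(bt$pelvis$category == 1L)), 0)
})

test_that("no bump means an empty impingement map", {
  model <- make_hip_fixture(fixture_spec(mesh_edge_length = 3))
  prof <- compute_cca_profile(model, hold_activity(), map_params)
  bt <- map_impingement(model, prof, cca_categories(), map_params, "BTBI")
  expect_true(all(bt$pelvis$category == 0L))
  expect_true(all(bt$femur$category == 0L))
  expect_equal(nrow(bt$pelvis$provenance), 0L)
})

test_that("pre-collapse impinged sets nest across fractions", {
  spec <- bump_spec_for_reach(-2, edge = 2.5)
  model <- make_hip_fixture(spec)
  prof <- compute_cca_profile(model, hold_activity(), map_params)
  bt <- map_impingement(model, prof, cca_categories(), map_params, "BTBI")
  for (m in list(bt$pelvis, bt$femur)) {
    sets <- lapply(c(0.25, 0.5, 0.75, 1), itf_faces, map = m)
    for (j in 1:3) expect_true(all(sets[[j]] %in% sets[[j + 1]]))
  }
})

fake_map <- function(faces, ratios, n_faces = 50, bone = "pelvis",
                     mode = "ITBI") {
  ev <- mapply(function(f, r) list(faces = f, ratio = r, activity = "a",
                                   posture = 1L),
               faces, ratios, SIMPLIFY = FALSE)
  impingemap:::.events_to_map(bone, mode, n_faces, ev, cca_categories())
}

test_that("the common-face filter removes exactly the shared faces", {
  itbi <- fake_map(list(c(1L, 2L, 3L)), list(0.2))
  btbi <- fake_map(list(c(2L, 3L, 4L)), list(0.6), mode = "BTBI")
  filt <- filter_itbi(itbi, btbi)
  expect_equal(which(filt$category > 0L), 1L)
  expect_equal(attr(filt, "filtered_faces"), c(2L, 3L))
  # disjoint maps: no-op
  d <- filter_itbi(fake_map(list(1:3), list(0.2)),
                   fake_map(list(7:9), list(0.2), mode = "BTBI"))
  expect_equal(which(d$category > 0L), 1:3)
  # full overlap empties the map
  e <- filter_itbi(fake_map(list(1:3), list(0.2)),
                   fake_map(list(1:5), list(0.9), mode = "BTBI"))
  expect_equal(sum(e$category > 0L), 0L)
  expect_error(filter_itbi(itbi, fake_map(list(1L), list(0.1),
                                          bone = "femur")),
               "different bones")
})

test_that("combining maps keeps the most severe category", {
  a <- fake_map(list(1:3), list(0.9))            # blue
  b <- fake_map(list(c(2L, 8L)), list(0.1), mode = "BTBI")  # red
  comb <- combine_maps(a, b)
  expect_equal(comb$category[1], 4L)
  expect_equal(comb$category[2], 1L)   # red beats blue
  expect_equal(comb$category[8], 1L)
  comb2 <- combine_maps(b, a)
  expect_equal(comb$category, comb2$category)            # commutative
  expect_equal(combine_maps(comb, comb)$category, comb$category)  # idempotent
})

test_that("a mirrored model yields the mirrored impingement map", {
  # out-of-plane bump so the mirror is non-trivial
  rs <- 9; rb <- 5; D <- 55
  gamma <- (28 + asin((rs + rb) / D) * 180 / pi) * pi / 180
  u <- c(sin(gamma) * cos(0.5), sin(gamma) * sin(0.5), -cos(gamma))
  spec <- fixture_spec(mesh_edge_length = 3, shaft_radius = rs,
                       shaft_end = 57, plate_distance = 60,
                       bump = list(direction = u, height = 10, radius = rb))
  model <- make_hip_fixture(spec)
  mmodel <- model
  for (nm in c("pelvis", "femur", "stem", "liner"))
    mmodel[[nm]] <- mirror_mesh(model[[nm]])
  mmodel$hip_center <- mirror_point(model$hip_center)
  mmodel$femur_axis_point <- mirror_point(model$femur_axis_point)

  act <- activity("ab", posture(0, 8, 0), posture(0.01, 8, 0))
  mact <- activity("ab", posture(0, -8, 0), posture(0.01, -8, 0))
  params <- sweep_params(dt_pos = 5, dt_alpha = 2, n_alpha = 31,
                         dt_con = 45)
  bt <- map_impingement(model, compute_cca_profile(model, act, params),
                        cca_categories(), params, "BTBI")
  mbt <- map_impingement(mmodel, compute_cca_profile(mmodel, mact, params),
                         cca_categories(), params, "BTBI")
  expect_identical(mbt$pelvis$category, bt$pelvis$category)
  expect_identical(mbt$femur$category, bt$femur$category)
})
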