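test_that("closest point hits vertices and perpendicular feet exactly", {
  s <- tri_surface(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                   rbind(c(1, 2, 3)))
  at_vertex <- closest_point_on_surface(s, c(10, 0, 0))
  expect_equal(as.numeric(at_vertex$point), c(10, 0, 0))
  expect_equal(at_vertex$distance, 0)

  above <- closest_point_on_surface(s, c(2, 3, 2))
  expect_equal(as.numeric(above$point), c(2, 3, 0), tolerance = 1e-12)
  expect_equal(above$distance, 2, tolerance = 1e-12)

  # beyond an edge: the foot is on the edge, not the face plane
  beyond <- closest_point_on_surface(s, c(-3, 4, 0))
  expect_equal(as.numeric(beyond$point), c(0, 4, 0), tolerance = 1e-12)
  expect_equal(beyond$distance, 3, tolerance = 1e-12)
})

test_that("tree-accelerated distances match the brute-force oracle", {
  s <- sphere_mesh(r = 40, n_phi = 10, n_theta = 20)
  set.seed(77)
  pts <- matrix(rnorm(3 * 60, sd = 50), ncol = 3)
  fast <- closest_point_on_surface(s, pts)
  for (i in seq_len(nrow(pts))) {
    expect_equal(fast$distance[i], brute_closest_point(s, pts[i, ]),
                 tolerance = 1e-9)
  }
  # never farther than the nearest vertex
  for (i in seq_len(nrow(pts))) {
    expect_lte(fast$distance[i],
               min(sqrt(rowSums(sweep(s$vertices, 2, pts[i, ])^2))) + 1e-12)
  }
})

test_that("degenerate meshes are rejected", {
  expect_error(tri_surface(matrix(numeric(0), 0, 3),
                           matrix(integer(0), 0, 3)), "empty")
  expect_error(tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                           rbind(c(1, 2, 3))), "degenerate triangle")
  expect_error(tri_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                           rbind(c(1, 2, 4))), "out of range")
})

test_that("polyline resampling gives uniform spacing with endpoints kept", {
  seg <- polyline3(rbind(c(0, 0, 0), c(10, 0, 0)))
  rs <- resample_polyline(seg, 0.25)
  expect_identical(nrow(rs), 41L)
  spacing <- diff(rs[, 1])
  expect_equal(spacing, rep(0.25, 40), tolerance = 1e-12)

  # curve shorter than the step: the two endpoints only
  short <- polyline3(rbind(c(0, 0, 0), c(0.1, 0, 0)))
  expect_identical(nrow(resample_polyline(short, 0.25)), 2L)

  # arc length preserved within one step, for random smooth polylines
  for (seed in 1:10) {
    set.seed(seed)
    t_ <- seq(0, 1, length.out = 300)
    coef <- matrix(rnorm(18, sd = 10), ncol = 3)
    poly <- polyline3(cbind(
      coef[1, 1] * sin(2 * pi * t_) + coef[2, 1] * t_ * 20,
      coef[3, 2] * cos(2 * pi * t_) + coef[4, 2] * sin(4 * pi * t_),
      coef[5, 3] * sin(3 * pi * t_) + coef[6, 3] * t_ * 10))
    L <- arc_length(poly)
    expect_lte(arc_length(resample_polyline(poly, 0.25)), L + 1e-12)
    expect_gte(arc_length(resample_polyline(poly, 0.25)), L - 0.25)
  }
  expect_error(resample_polyline(seg, 0), "step")
  expect_error(resample_polyline(seg, -1), "step")
})

test_that("resampled length converges monotonely to the true length", {
  theta <- seq(0, pi, length.out = 200)
  helix <- polyline3(cbind(40 * cos(theta), 40 * sin(theta), 10 * theta))
  L <- arc_length(helix)
  lens <- vapply(c(1, 0.5, 0.25, 0.125),
                 function(st) arc_length(resample_polyline(helix, st)),
                 numeric(1))
  expect_true(all(lens <= L + 1e-12))
  expect_true(all(diff(lens) >= -1e-12))     # finer step, longer length
  expect_lt(L - lens[4], 0.125)
})

test_that("resampling an already step-uniform curve is a no-op", {
  theta <- seq(0, pi, length.out = 500)
  arc <- polyline3(cbind(50 * cos(theta), 50 * sin(theta), 0))
  once <- resample_polyline(arc, 0.25)
  twice <- resample_polyline(once, 0.25)
  expect_identical(as.matrix(once), as.matrix(twice))
})

test_that("projection recovers on-surface curves and is idempotent", {
  s <- flat_patch()
  flat_curve <- polyline3(cbind(seq(0, 100, by = 5), 2, 0))
  expect_lt(max(abs(as.matrix(project_polyline(s, flat_curve)) -
                      as.matrix(flat_curve))), 1e-9)
  lifted <- polyline3(cbind(seq(0, 100, by = 5), 2, 7))
  dropped <- project_polyline(s, lifted)
  expect_lt(max(abs(as.matrix(dropped) - as.matrix(flat_curve))), 1e-9)

  sph <- sphere_mesh(r = 50, n_phi = 40, n_theta = 80)
  t_ <- seq(0.2, 1.2, length.out = 60)
  outside <- polyline3(60 * cbind(cos(t_), sin(t_), 0.3))
  p1 <- project_polyline(sph, outside)
  p2 <- project_polyline(sph, p1)
  expect_lt(max(abs(as.matrix(p1) - as.matrix(p2))), 1e-9)
  # radial projection oracle: feet lie near radius r, within the
  # chord-height bound computed from the mesh's longest edge
  tr <- sph$triangles
  edges <- rbind(cbind(tr[, 1], tr[, 2]), cbind(tr[, 2], tr[, 3]),
                 cbind(tr[, 3], tr[, 1]))
  max_edge <- sqrt(max(rowSums(
    (sph$vertices[edges[, 1], ] - sph$vertices[edges[, 2], ])^2)))
  sagitta <- max_edge^2 / (8 * 50)
  expect_lt(max(abs(sqrt(rowSums(as.matrix(p1)^2)) - 50)), sagitta + 1e-9)
})

test_that("meshes round-trip through ASCII STL, binary STL and PLY", {
  s <- sphere_mesh(r = 20, n_phi = 6, n_theta = 12)
  for (args in list(list(ext = ".stl", binary = FALSE),
                    list(ext = ".stl", binary = TRUE),
                    list(ext = ".ply", binary = FALSE))) {
    path <- withr::local_tempfile(fileext = args$ext)
    write_mesh(s, path, binary = args$binary)
    back <- read_mesh(path)
    expect_identical(nrow(back$triangles), nrow(s$triangles))
    # same geometry: every original vertex has a zero-distance closest point
    cp <- closest_point_on_surface(back, s$vertices)
    tol <- if (args$binary) 1e-4 else 1e-6  # binary STL stores float32
    expect_lt(max(cp$distance), tol)
  }
  expect_error(read_mesh(withr::local_tempfile(fileext = ".obj")),
               "unknown mesh format")
})

test_that("curves round-trip through CSV with labels", {
  cur <- polyline3(matrix(rnorm(30), ncol = 3), label = "coronal")
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(cur, path)
  back <- read_curve(path)
  expect_identical(curve_label(back), "coronal")
  expect_equal(as.matrix(back), as.matrix(cur), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("mesh plane sections lie exactly on the surface", {
  ph <- small_phantom()
  sec <- mesh_plane_section(ph$surface, "x", 10)
  d <- closest_point_on_surface(ph$surface, as.matrix(sec))$distance
  expect_lt(max(d), 1e-9)
  # resampling a section keeps it on the surface (segments lie in facets)
  rs <- resample_polyline(sec, 0.25)
  d2 <- closest_point_on_surface(ph$surface, as.matrix(rs))$distance
  expect_lt(max(d2), 1e-9)
})
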