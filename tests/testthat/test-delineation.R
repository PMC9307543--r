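# Dense independent strip integration between two curves, used as the
# area oracle: sample both at very fine normalized arc and sum exact
# trapezoid slivers via the cross product.
dense_strip_area <- function(a_fun, b_fun, n = 20000L) {
  u <- seq(0, 1, length.out = n)
  a <- a_fun(u); b <- b_fun(u)
  area <- 0
  for (i in seq_len(n - 1L)) {
    p <- rbind(a[i, ], a[i + 1L, ], b[i + 1L, ], b[i, ])
    v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]; v3 <- p[4, ] - p[1, ]
    cr <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                           x[3] * y[1] - x[1] * y[3],
                           x[1] * y[2] - x[2] * y[1])
    area <- area + 0.5 * sqrt(sum(cr(v1, v2)^2)) +
      0.5 * sqrt(sum(cr(v2, v3)^2))
  }
  area
}

test_that("coincident and parallel planar curves give exact clipping/area", {
  ref <- polyline3(cbind(seq(0, 100, by = 1), 0, 0))
  same <- clip_to_overlap(ref, ref)
  expect_equal(same$overlap_length, 100, tolerance = 1e-12)
  expect_equal(spanned_area(same$reference, same$drawn), 0,
               tolerance = 1e-9)

  # parallel copy offset 2.4 mm, full overlap: a 100 x 2.4 rectangle
  off <- polyline3(cbind(seq(0, 100, by = 1), 2.4, 0))
  cl <- clip_to_overlap(ref, off)
  expect_equal(cl$overlap_length, 100, tolerance = 1e-9)
  expect_equal(spanned_area(cl$reference, cl$drawn), 240, tolerance = 1e-6)
})

test_that("partial overlap clips to the shared span", {
  ref <- polyline3(cbind(seq(0, 100, by = 1), 0, 0))
  shifted <- polyline3(cbind(seq(50, 150, by = 1), 3, 0))
  cl <- clip_to_overlap(ref, shifted)
  expect_equal(cl$overlap_length, 50, tolerance = 1e-9)
  expect_equal(range(as.matrix(cl$reference)[, 1]), c(50, 100),
               tolerance = 1e-9)
  expect_equal(range(as.matrix(cl$drawn)[, 1]), c(50, 100),
               tolerance = 1e-9)
  expect_equal(spanned_area(cl$reference, cl$drawn), 150, tolerance = 1e-6)

  # drawn entirely beyond the reference end: no usable overlap
  beyond <- polyline3(cbind(seq(110, 150, by = 1), 3, 0))
  expect_error(clip_to_overlap(ref, beyond), "no overlap")
})

test_that("spanned area matches dense integration on concentric arcs", {
  ang <- seq(0, pi / 3, length.out = 400)
  inner <- polyline3(cbind(50 * cos(ang), 50 * sin(ang), 0))
  outer <- polyline3(cbind(52 * cos(ang), 52 * sin(ang), 0))
  got <- spanned_area(inner, outer, step = 0.25)
  # closed form for the annular sector: (pi/3) * (52^2 - 50^2) / 2
  expect_equal(got, (pi / 3) * (52^2 - 50^2) / 2, tolerance = 0.005)
  # independent dense-resampling oracle
  oracle <- dense_strip_area(
    function(u) cbind(50 * cos(u * pi / 3), 50 * sin(u * pi / 3), 0),
    function(u) cbind(52 * cos(u * pi / 3), 52 * sin(u * pi / 3), 0))
  expect_equal(got, oracle, tolerance = 0.005)
})

test_that("full pipeline reproduces planar analytic distances", {
  s <- flat_patch()
  ref <- polyline3(cbind(seq(0, 100, by = 0.5), 0, 0), label = "ref")
  for (h in c(0.5, 2.4, 5)) {
    drawn <- polyline3(cbind(seq(0, 100, by = 0.5), h, 0), label = "drawn")
    e <- delineation_distance(s, ref, drawn, step = 0.25)
    expect_lt(abs(e$distance - h) / h, 1e-6)
    expect_equal(e$overlap_fraction, 1, tolerance = 1e-9)
  }
  half <- polyline3(cbind(seq(50, 150, by = 0.5), 3, 0), label = "half")
  e <- delineation_distance(s, ref, half, step = 0.25)
  expect_equal(e$overlap_length, 50, tolerance = 1e-6)
  expect_equal(e$spanned_area, 150, tolerance = 1e-3)
  expect_equal(e$distance, 3, tolerance = 1e-6)
  expect_equal(e$overlap_fraction, 0.5, tolerance = 1e-6)
  # identical curves: d = 0
  e0 <- delineation_distance(s, ref, ref, step = 0.25)
  expect_lt(e0$distance, 1e-9)
})

test_that("d = S_A / D_L holds exactly on the result object", {
  s <- flat_patch()
  ref <- polyline3(cbind(seq(0, 80, by = 0.5), 0, 0))
  drawn <- polyline3(cbind(seq(5, 70, by = 0.5), 1 + 0.3 * sin(seq(5, 70, by = 0.5) / 9), 0))
  e <- delineation_distance(s, ref, drawn)
  expect_identical(e$distance, e$spanned_area / e$overlap_length)
  expect_gte(e$spanned_area, 0)
  expect_gte(e$overlap_length, 0)
  expect_lte(e$overlap_fraction, 1)
})

test_that("halving the step changes d by less than 0.1% on smooth curves", {
  sph <- sphere_mesh(r = 50, n_phi = 60, n_theta = 120)
  lat_ref <- 0.5; lat_drawn <- 0.55
  ang <- seq(-1, 1, length.out = 800)
  ref <- polyline3(50 * cbind(cos(lat_ref) * cos(ang),
                              cos(lat_ref) * sin(ang),
                              sin(lat_ref) + 0 * ang))
  drawn <- polyline3(50 * cbind(cos(lat_drawn) * cos(ang),
                                cos(lat_drawn) * sin(ang),
                                sin(lat_drawn) + 0 * ang))
  d1 <- delineation_distance(sph, ref, drawn, step = 0.25)$distance
  d2 <- delineation_distance(sph, ref, drawn, step = 0.125)$distance
  expect_lt(abs(d1 - d2) / d1, 0.001)
})

test_that("the metric is rigid-invariant and scales linearly", {
  s <- flat_patch()
  ref <- polyline3(cbind(seq(0, 100, by = 0.5), 0, 0))
  drawn <- polyline3(cbind(seq(10, 90, by = 0.5), 2, 0))
  base <- delineation_distance(s, ref, drawn)

  for (seed in c(5, 17)) {
    g <- random_rigid_transform(seed)
    s_g <- tri_surface(transform_points(g, s$vertices), s$triangles)
    ref_g <- polyline3(transform_points(g, as.matrix(ref)))
    drawn_g <- polyline3(transform_points(g, as.matrix(drawn)))
    moved <- delineation_distance(s_g, ref_g, drawn_g)
    expect_equal(moved$distance, base$distance, tolerance = 1e-9)
    expect_equal(moved$spanned_area, base$spanned_area, tolerance = 1e-6)
  }

  k <- 2.5
  s_k <- tri_surface(k * s$vertices, s$triangles)
  scaled <- delineation_distance(s_k, polyline3(k * as.matrix(ref)),
                                 polyline3(k * as.matrix(drawn)),
                                 step = 0.25 * k)
  expect_equal(scaled$distance, k * base$distance, tolerance = 1e-6)
})
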