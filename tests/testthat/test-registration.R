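tetra_points <- function() {
  labeled_points(c("a", "b", "c", "d"),
                 rbind(c(0, 0, 0), c(30, 0, 0), c(0, 25, 0), c(5, 5, 20)))
}

test_that("registering a set to itself gives identity and FRE 0", {
  ps <- tetra_points()
  reg <- register_paired_points(ps, ps)
  expect_transform_equal(reg$transform, rt_identity())
  expect_lt(reg$fre, 1e-12)
  expect_length(reg$residuals, 4L)
})

test_that("exact rigid motions are recovered with FRE below 1e-9 mm", {
  ps <- tetra_points()
  applied <- rigid_transform(rot_z(pi / 2), c(5, 0, 0))
  moved <- labeled_points(ps$label,
                          transform_points(applied, point_matrix(ps)))
  reg <- register_paired_points(ps, moved)
  expect_lt(reg$fre, 1e-9)
  expect_transform_equal(reg$transform, applied)
  # label matching is by name, not order
  shuffled <- moved[c(3, 1, 4, 2), ]
  class(shuffled) <- class(moved)
  reg2 <- register_paired_points(ps, shuffled)
  expect_transform_equal(reg2$transform, applied)
})

test_that("determinant correction rejects the reflected optimum", {
  # near-planar set whose noisy counterpart is (almost) its mirror image:
  # unconstrained orthogonal Procrustes prefers the reflection
  set.seed(401)
  base <- cbind(matrix(runif(10, -30, 30), ncol = 2), rnorm(5, sd = 0.4))
  moving <- labeled_points(letters[1:5], base)
  mirrored <- base
  mirrored[, 3] <- -mirrored[, 3]
  fixed <- labeled_points(letters[1:5], mirrored + rnorm(15, sd = 0.05))
  reg <- register_paired_points(moving, fixed)
  expect_equal(det(rt_rotation(reg$transform)), 1, tolerance = 1e-9)

  # oracle: evaluate both sign choices of the SVD solution by brute force
  m <- point_matrix(moving); f <- point_matrix(fixed)
  m0 <- sweep(m, 2, colMeans(m)); f0 <- sweep(f, 2, colMeans(f))
  sv <- svd(crossprod(m0, f0))
  cost <- function(r) {
    tv <- colMeans(f) - as.numeric(r %*% colMeans(m))
    sum((sweep(m %*% t(r), 2, tv, "+") - f)^2)
  }
  r_plus <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  r_refl <- sv$v %*% diag(c(1, 1, -sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  expect_equal(det(r_refl), -1, tolerance = 1e-9)
  # the returned rotation is the proper-rotation optimum...
  expect_equal(cost(rt_rotation(reg$transform)), cost(r_plus),
               tolerance = 1e-9)
  # ...and pays a residual at least as large as the reflected solution
  expect_gte(sum(reg$residuals^2) + 1e-12, cost(r_refl))
})

test_that("degenerate registrations are rejected", {
  two <- labeled_points(c("a", "b"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(register_paired_points(two, two), "at least 3")
  line <- labeled_points(c("a", "b", "c"),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(register_paired_points(line, line), "collinear")
  ps <- tetra_points()
  other <- labeled_points(c("a", "b", "c", "e"), point_matrix(ps))
  expect_error(register_paired_points(ps, other), "labels")
})

test_that("FRE is the RMS of the residuals", {
  expect_identical(fiducial_registration_error(rep(0, 4)), 0)
  expect_identical(fiducial_registration_error(rep(2, 4)), 2)
  expect_equal(fiducial_registration_error(c(3, 4)), sqrt(12.5))
  expect_error(fiducial_registration_error(numeric(0)), "degenerate")
  # the result object satisfies fre == rms(residuals)
  ps <- tetra_points()
  noisy <- perturb_points(ps, 0.5, seed = 7)
  reg <- register_paired_points(ps, noisy)
  expect_equal(reg$fre, sqrt(mean(reg$residuals^2)), tolerance = 1e-12)
})

test_that("TRE is zero for exact transforms and |e| for translation error", {
  targets <- labeled_points(c("t1", "t2", "t3"),
                            rbind(c(50, 0, 0), c(0, 60, 0), c(10, 10, 40)))
  exact <- target_registration_error(rt_identity(), targets, targets)
  expect_equal(exact$tre, 0)
  off <- rigid_transform(diag(3), c(3, 4, 0))
  tre <- target_registration_error(off, targets, targets)
  expect_equal(unname(tre$per_target), rep(5, 3), tolerance = 1e-12)
  expect_equal(tre$tre, 5, tolerance = 1e-12)
})

test_that("registration is equivariant and FRE rigid-invariant", {
  ps <- tetra_points()
  fixed <- perturb_points(ps, 0.3, seed = 21)
  reg <- register_paired_points(ps, fixed)
  probe <- matrix(rnorm(15, sd = 40), ncol = 3)
  for (seed in 1:20) {
    g <- random_rigid_transform(seed)
    moved <- labeled_points(ps$label, transform_points(g, point_matrix(ps)))
    reg2 <- register_paired_points(moved, fixed)
    # registering g-moved points must equal (g^-1 then original fit)
    expect_lt(max(abs(
      transform_points(reg2$transform, transform_points(g, probe)) -
        transform_points(reg$transform, probe))), 1e-9)
    # FRE invariant when the same motion is applied to both sides
    both <- register_paired_points(
      moved, labeled_points(ps$label,
                            transform_points(g, point_matrix(fixed))))
    expect_equal(both$fre, reg$fre, tolerance = 1e-9)
  }
})

test_that("fitted transform beats 10^4 random rigid transforms", {
  ps <- tetra_points()
  cost <- function(t_, m, f) sum((transform_points(t_, m) - f)^2)
  for (trial in 1:3) {
    fixed <- perturb_points(
      labeled_points(ps$label,
                     transform_points(random_rigid_transform(trial + 50),
                                      point_matrix(ps))),
      0.8, seed = trial)
    reg <- register_paired_points(ps, fixed)
    fit_cost <- cost(reg$transform, point_matrix(ps), point_matrix(fixed))
    rand_costs <- vapply(seq_len(1e4), function(i) {
      cost(random_rigid_transform(i + 7919 * trial),
           point_matrix(ps), point_matrix(fixed))
    }, numeric(1))
    expect_lte(fit_cost, min(rand_costs))
  }
})

test_that("noise propagation: zero sigma is exact, remote targets suffer", {
  lm <- small_phantom()$anatomical_landmarks
  targets <- labeled_points(
    c("anterior", "middle", "posterior"),
    rbind(c(60, 0, 20), c(0, 0, 45), c(-60, 0, 20)))
  silent <- fre_tre_monte_carlo(lm, targets, sigma = 0, n_reps = 5, seed = 1)
  expect_true(all(silent$fre < 1e-12))
  expect_true(all(silent$tre_per_target < 1e-12))

  mc <- fre_tre_monte_carlo(lm, targets, sigma = 0.5, n_reps = 500, seed = 2)
  means <- colMeans(mc$tre_per_target)
  # anterior landmark cluster: error grows with distance from the cluster
  expect_lt(means[["anterior"]], means[["middle"]])
  expect_lt(means[["middle"]], means[["posterior"]])
  # reproducible given the seed
  mc2 <- fre_tre_monte_carlo(lm, targets, sigma = 0.5, n_reps = 500, seed = 2)
  expect_identical(mc$fre, mc2$fre)
})

test_that("point sets round-trip through CSV and FCSV (RAS handled)", {
  ps <- tetra_points()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_points(ps, csv)
  expect_equal(point_matrix(read_points(csv)), point_matrix(ps),
               tolerance = 1e-9)

  fcsv <- withr::local_tempfile(fileext = ".fcsv")
  write_points(ps, fcsv)
  back <- read_points(fcsv)
  expect_identical(back$label, ps$label)
  expect_equal(point_matrix(back), point_matrix(ps), tolerance = 1e-6)

  # an RAS-declared file is converted to the internal LPS convention
  ras <- withr::local_tempfile(fileext = ".fcsv")
  lines <- readLines(fcsv)
  lines <- sub("CoordinateSystem = LPS", "CoordinateSystem = RAS", lines)
  writeLines(lines, ras)
  conv <- read_points(ras)
  expect_equal(conv$x, -ps$x, tolerance = 1e-6)
  expect_equal(conv$y, -ps$y, tolerance = 1e-6)
  expect_equal(conv$z, ps$z, tolerance = 1e-6)
})
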