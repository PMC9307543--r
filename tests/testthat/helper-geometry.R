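# Shared fixtures, built in code.

# Flat rectangular mesh in the z = 0 plane covering [x0, x1] x [y0, y1],
# subdivided into nx x ny quads (two triangles each).
flat_patch <- function(x0 = -10, x1 = 160, y0 = -10, y1 = 10,
                       nx = 34, ny = 4) {
  xs <- seq(x0, x1, length.out = nx + 1)
  ys <- seq(y0, y1, length.out = ny + 1)
  g <- expand.grid(x = xs, y = ys)
  verts <- cbind(g$x, g$y, 0)
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      tris[[length(tris) + 1L]] <- rbind(
        c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
        c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
    }
  }
  tri_surface(verts, do.call(rbind, tris))
}

# UV-sphere mesh of radius r centred at the origin.
sphere_mesh <- function(r = 50, n_phi = 24, n_theta = 48) {
  phi <- seq(-pi / 2 * (1 - 1 / n_phi), pi / 2 * (1 - 1 / n_phi),
             length.out = n_phi)
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  g <- expand.grid(theta = theta, phi = phi)
  verts <- cbind(r * cos(g$phi) * cos(g$theta),
                 r * cos(g$phi) * sin(g$theta),
                 r * sin(g$phi))
  south <- c(0, 0, -r); north <- c(0, 0, r)
  verts <- rbind(verts, south, north)
  si <- nrow(verts) - 1L; ni <- nrow(verts)
  vid <- function(ip, it) (ip - 1L) * n_theta + ((it - 1L) %% n_theta) + 1L
  tris <- list()
  for (ip in seq_len(n_phi - 1L)) {
    for (it in seq_len(n_theta)) {
      tris[[length(tris) + 1L]] <- rbind(
        c(vid(ip, it), vid(ip, it + 1L), vid(ip + 1L, it + 1L)),
        c(vid(ip, it), vid(ip + 1L, it + 1L), vid(ip + 1L, it)))
    }
  }
  for (it in seq_len(n_theta)) {
    tris[[length(tris) + 1L]] <- rbind(
      c(si, vid(1L, it + 1L), vid(1L, it)),
      c(ni, vid(n_phi, it), vid(n_phi, it + 1L)))
  }
  tri_surface(verts, do.call(rbind, tris))
}

# Brute-force closest point on a mesh: exact point-triangle distance against
# every triangle, independent of the compiled path.
brute_closest_point <- function(surface, p) {
  v <- surface$vertices
  tr <- surface$triangles
  best <- Inf
  for (t_ in seq_len(nrow(tr))) {
    d <- point_triangle_distance(p, v[tr[t_, 1], ], v[tr[t_, 2], ],
                                 v[tr[t_, 3], ])
    if (d < best) best <- d
  }
  best
}

# Exact point-triangle distance via constrained barycentric minimization,
# written independently of the package's region-classification kernel.
point_triangle_distance <- function(p, a, b, c) {
  # candidates: interior critical point, three edges, three vertices
  e1 <- b - a; e2 <- c - a
  m <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum(e1 * (p - a)), sum(e2 * (p - a)))
  cand <- list(a, b, c)
  uv <- tryCatch(solve(m, rhs), error = function(e) NULL)
  if (!is.null(uv) && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
    cand[[length(cand) + 1L]] <- a + uv[1] * e1 + uv[2] * e2
  }
  seg_foot <- function(q0, q1) {
    t_ <- sum((p - q0) * (q1 - q0)) / sum((q1 - q0)^2)
    q0 + min(max(t_, 0), 1) * (q1 - q0)
  }
  cand <- c(cand, list(seg_foot(a, b), seg_foot(b, c), seg_foot(c, a)))
  min(vapply(cand, function(q) sqrt(sum((p - q)^2)), numeric(1)))
}

# A small phantom for fast tests.
small_phantom <- function(seed = 11, n_fiducials = 10, level = 3) {
  make_phantom(phantom_spec(n_fiducials = n_fiducials,
                            tessellation_level = level),
               seed = seed, id = "SKtest")
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(unclass(a) - unclass(b))), tol)
}

# Vectorized exhaustive scan: exact distance from each query point to every
# triangle (candidates: interior critical point, clamped edge feet,
# vertices), minimized over triangles. Independent of the compiled kernel.
brute_closest_all <- function(surface, pts) {
  v <- surface$vertices
  tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  d11 <- rowSums(e1 * e1); d22 <- rowSums(e2 * e2); d12 <- rowSums(e1 * e2)
  det_ <- d11 * d22 - d12 * d12
  seg_d2 <- function(p, q0, dq, len2) {
    t_ <- pmin(pmax(rowSums(sweep(q0, 2, p, "-") * -dq) / len2, 0), 1)
    foot <- q0 + dq * t_
    rowSums(sweep(foot, 2, p, "-")^2)
  }
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    ap <- sweep(a, 2, p, "-")
    r1 <- -rowSums(ap * e1); r2 <- -rowSums(ap * e2)
    u <- (d22 * r1 - d12 * r2) / det_
    w <- (d11 * r2 - d12 * r1) / det_
    inside <- u >= 0 & w >= 0 & (u + w) <= 1
    interior <- rowSums((ap + e1 * u + e2 * w)^2)
    d2 <- pmin(seg_d2(p, a, e1, d11),
               seg_d2(p, b, c_ - b, rowSums((c_ - b)^2)),
               seg_d2(p, a, e2, d22))
    d2[inside] <- pmin(d2[inside], interior[inside])
    sqrt(min(d2))
  }, numeric(1))
}
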