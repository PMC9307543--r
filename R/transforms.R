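#' Rigid transforms in 3-D
#'
#' A `rigid_transform` is a proper rigid motion of 3-D space: a rotation
#' (orthonormal, determinant +1) followed by a translation in millimetres.
#' It is stored as a 4x4 homogeneous matrix so that transforms can be
#' serialized unambiguously and chained by matrix multiplication.
#'
#' @param rotation 3x3 orthonormal rotation matrix with determinant +1.
#' @param translation numeric length-3 translation vector (mm).
#' @return An object of class `rigid_transform` (a 4x4 homogeneous matrix).
#' @examples
#' t1 <- rigid_transform(rot_z(pi / 2), c(5, 0, 0))
#' transform_points(t1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    stop("invalid transform: rotation must be 3x3 and translation length 3",
         call. = FALSE)
  }
  check_rotation(rotation)
  if (!all(is.finite(translation))) {
    stop("invalid transform: non-finite translation", call. = FALSE)
  }
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  structure(m, class = "rigid_transform")
}

# Orthonormality / determinant check shared by constructors and readers.
check_rotation <- function(rotation, tol = 1e-9) {
  if (!all(is.finite(rotation))) {
    stop("invalid transform: non-finite rotation", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop("invalid transform: rotation is not orthonormal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > tol) {
    stop("invalid transform: rotation determinant is not +1 (reflection?)",
         call. = FALSE)
  }
  invisible(rotation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> (mm)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname rigid_transform
#' @param t,x a `rigid_transform`.
#' @export
rt_rotation <- function(t) unclass(t)[1:3, 1:3, drop = FALSE]

#' @rdname rigid_transform
#' @export
rt_translation <- function(t) unclass(t)[1:3, 4]

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' @rdname rigid_transform
#' @export
is_rigid_transform <- function(x) inherits(x, "rigid_transform")

as_rigid_transform <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L)) ||
      max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12) {
    stop("invalid transform: expected a 4x4 homogeneous matrix", call. = FALSE)
  }
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Elementary rotations
#'
#' Right-handed rotations about the coordinate axes, in radians.
#'
#' @param angle rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rot_z <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

#' Compose two rigid transforms
#'
#' Returns the transform that applies `first`, then `second`:
#' `transform_points(compose(a, b), p)` equals
#' `transform_points(b, transform_points(a, p))`.
#'
#' @param first,second `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose <- function(first, second) {
  stopifnot(is_rigid_transform(first), is_rigid_transform(second))
  m <- unclass(second) %*% unclass(first)
  # re-orthonormalize lazily: long chains accumulate rounding at ~1e-15/step
  as_rigid_transform(m)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return The inverse `rigid_transform`, so `compose(t, invert(t))` is the
#'   identity to numerical precision.
#' @export
invert <- function(t) {
  stopifnot(is_rigid_transform(t))
  r <- rt_rotation(t)
  rigid_transform(t(r), -t(r) %*% rt_translation(t))
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param points an N x 3 numeric matrix of point coordinates in mm (a bare
#'   length-3 vector is accepted for a single point). An empty (0-row)
#'   matrix is returned unchanged.
#' @return The transformed points, same shape as the input matrix.
#' @export
transform_points <- function(t, points) {
  stopifnot(is_rigid_transform(t))
  pts <- as_point_matrix(points)
  if (nrow(pts) == 0L) return(pts)
  if (!all(is.finite(pts))) {
    stop("transform_points: non-finite coordinates", call. = FALSE)
  }
  out <- pts %*% t(rt_rotation(t))
  out <- sweep(out, 2L, rt_translation(t), "+")
  dimnames(out) <- dimnames(pts)
  out
}

# Coerce a length-3 vector or N x 3 matrix/data.frame to an N x 3 matrix.
as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) == 0L) return(matrix(numeric(0), 0, 3))
    if (length(points) != 3L) {
      stop("points must be a length-3 vector or an N x 3 matrix",
           call. = FALSE)
    }
    return(matrix(as.numeric(points), 1, 3))
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    stop("points must have 3 columns (x, y, z in mm)", call. = FALSE)
  }
  storage.mode(points) <- "double"
  points
}

#' Read and write rigid-transform files
#'
#' Plain-text interchange format for a rigid transform between two named
#' coordinate frames: a `from: <frame>` line, a `to: <frame>` line, then the
#' four rows of the 4x4 homogeneous matrix (row-major, units mm), whitespace
#' separated. Lines starting with `#` are ignored. The reader validates that
#' the rotation block is orthonormal with determinant +1.
#'
#' @param path file path.
#' @param t a `rigid_transform`.
#' @param from,to frame names recorded in the file.
#' @return `read_transform()` returns a list with elements `from`, `to` and
#'   `transform`; `write_transform()` returns `path` invisibly.
#' @export
write_transform <- function(t, path, from = "A", to = "B") {
  stopifnot(is_rigid_transform(t))
  rows <- apply(unclass(t), 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = " ")
  })
  writeLines(c(paste("from:", from), paste("to:", to), rows), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  from_i <- grep("^from:", lines)
  to_i <- grep("^to:", lines)
  if (length(from_i) != 1L || length(to_i) != 1L) {
    stop("transform file must have exactly one 'from:' and one 'to:' line",
         call. = FALSE)
  }
  from <- trimws(sub("^from:", "", lines[from_i]))
  to <- trimws(sub("^to:", "", lines[to_i]))
  num_lines <- lines[-c(from_i, to_i)]
  if (length(num_lines) != 4L) {
    stop("transform file must contain 4 matrix rows", call. = FALSE)
  }
  m <- do.call(rbind, lapply(num_lines, function(l) {
    as.numeric(strsplit(l, "[[:space:]]+")[[1]])
  }))
  if (!all(dim(m) == c(4L, 4L)) || anyNA(m)) {
    stop("transform file matrix is not 4x4 numeric", call. = FALSE)
  }
  list(from = from, to = to, transform = as_rigid_transform(m))
}

#' Random rigid transform (testing / simulation helper)
#'
#' Draws a uniformly random rotation (via QR decomposition of a Gaussian
#' matrix, sign-corrected to determinant +1) and a Gaussian translation.
#'
#' @param seed integer seed; the global RNG state is left untouched.
#' @param translation_sd standard deviation of each translation component (mm).
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(seed, translation_sd = 50) {
  with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    d[d == 0] <- 1
    q <- q %*% diag(d)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    rigid_transform(q, stats::rnorm(3, sd = translation_sd))
  })
}
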