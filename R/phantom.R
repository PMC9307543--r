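#' Synthetic skull-phantom generation
#'
#' Physical phantom studies of suture navigation use skull models carrying
#' annotated sutures, facial anatomical landmarks for patient alignment and
#' conical fiducial markers for an independent ground-truth registration.
#' [make_phantom()] builds a fully synthetic stand-in: a half-ellipsoid
#' "cranial vault" mesh whose midline section plays the sagittal suture,
#' whose transverse sections play the coronal and lambdoid sutures plus
#' three "virtual" sutures in between, with six landmarks clustered on the
#' anterior face region and a configurable number of fiducials spread over
#' the vault. Everything is deterministic given the seed. Real skull
#' meshes and curves can be supplied through the file readers instead.
#'
#' @name phantom
NULL

#' Phantom specification
#'
#' @param semi_axes half-ellipsoid semi-axes in mm, `c(ap, lateral,
#'   vertical)`. The default 70 x 55 x 50 mm approximates a young child's
#'   cranial vault (anterior-posterior length ~140 mm).
#' @param n_fiducials number of conical fiducial markers (>= 4); 10 and 8
#'   mirror the two physical skulls of a typical phantom pair.
#' @param tessellation_level mesh refinement level (>= 3); level L gives a
#'   hemisphere grid of `6L` rings by `12L` sectors (~2600 triangles at
#'   level 3).
#' @param coronal_fraction,lambdoid_fraction positions of the coronal and
#'   lambdoid section planes along the anterior(+)/posterior(-) axis, as
#'   fractions of the AP semi-axis.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(semi_axes = c(70, 55, 50),
                         n_fiducials = 10,
                         tessellation_level = 4,
                         coronal_fraction = 0.35,
                         lambdoid_fraction = -0.55) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0)) {
    stop("invalid parameter: semi_axes must be 3 positive lengths (mm)",
         call. = FALSE)
  }
  if (n_fiducials < 4L) {
    stop("invalid parameter: at least 4 fiducials required", call. = FALSE)
  }
  if (tessellation_level < 3L) {
    stop("invalid parameter: tessellation_level must be >= 3", call. = FALSE)
  }
  if (!(coronal_fraction > lambdoid_fraction) ||
      abs(coronal_fraction) >= 1 || abs(lambdoid_fraction) >= 1) {
    stop("invalid parameter: need -1 < lambdoid_fraction < coronal_fraction < 1",
         call. = FALSE)
  }
  structure(list(semi_axes = semi_axes,
                 n_fiducials = as.integer(n_fiducials),
                 tessellation_level = as.integer(tessellation_level),
                 coronal_fraction = coronal_fraction,
                 lambdoid_fraction = lambdoid_fraction),
            class = "phantom_spec")
}

# Upper-half ellipsoid mesh: latitude rings from the open rim (z = 0) to an
# apex vertex, triangles wound outward. x = anterior(+)/posterior(-),
# y = left/right, z = up. The azimuth grid is offset by half a sector so
# that no ring vertex sits exactly on the midline plane y = 0.
half_ellipsoid_mesh <- function(semi_axes, level) {
  n_phi <- 6L * level          # rim -> near-apex rings
  n_theta <- 12L * level       # azimuthal sectors
  phi <- seq(0, pi / 2 * (1 - 1 / n_phi), length.out = n_phi)  # elevation
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  grid <- expand.grid(theta = theta, phi = phi)
  verts <- cbind(semi_axes[1] * cos(grid$phi) * cos(grid$theta),
                 semi_axes[2] * cos(grid$phi) * sin(grid$theta),
                 semi_axes[3] * sin(grid$phi))
  apex <- c(0, 0, semi_axes[3])
  verts <- rbind(verts, apex)
  apex_i <- nrow(verts)
  vid <- function(i_phi, i_theta) {  # 1-based ring/sector -> vertex index
    (i_phi - 1L) * n_theta + ((i_theta - 1L) %% n_theta) + 1L
  }
  tris <- vector("list", n_phi * n_theta)
  k <- 1L
  for (i in seq_len(n_phi - 1L)) {
    for (j in seq_len(n_theta)) {
      v00 <- vid(i, j); v01 <- vid(i, j + 1L)
      v10 <- vid(i + 1L, j); v11 <- vid(i + 1L, j + 1L)
      tris[[k]] <- rbind(c(v00, v01, v11), c(v00, v11, v10))
      k <- k + 1L
    }
  }
  for (j in seq_len(n_theta)) {  # apex cap
    tris[[k]] <- rbind(c(vid(n_phi, j), vid(n_phi, j + 1L), apex_i))
    k <- k + 1L
  }
  tri_surface(verts, do.call(rbind, tris[seq_len(k - 1L)]))
}

# Point(s) on the analytic ellipsoid at azimuth theta, elevation phi.
ellipsoid_point <- function(semi_axes, theta, phi) {
  cbind(semi_axes[1] * cos(phi) * cos(theta),
        semi_axes[2] * cos(phi) * sin(theta),
        semi_axes[3] * sin(phi))
}

#' Generate a synthetic skull phantom
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed controlling fiducial placement.
#' @param id phantom identifier recorded on the object (e.g. `"SK1"`).
#' @return A `phantom_model` list with fields `surface` (`tri_surface`),
#'   `sutures` (named list of labelled `polyline3`: sagittal, coronal,
#'   lambdoid, virtual_1..3), `anatomical_landmarks` and `fiducials`
#'   (`labeled_points` on the surface), `patient_sensor_pose`
#'   (`rigid_transform`), plus `spec`, `seed` and `id`.
#' @examples
#' ph <- make_phantom(phantom_spec(n_fiducials = 8), seed = 7, id = "SK2")
#' names(ph$sutures)
#' @export
make_phantom <- function(spec = phantom_spec(), seed = 1L, id = "SK1") {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- spec$semi_axes
  surface <- half_ellipsoid_mesh(ax, spec$tessellation_level)

  # suture section planes: coronal (anterior), lambdoid (posterior), and 3
  # evenly spaced virtual sutures in between. Each suture is stored as the
  # exact mesh-plane section polyline: its vertices sit on mesh edges and
  # every segment lies inside one facet, so the curve (and any arc-length
  # resampling of it) lies exactly on the surface. The 0.25 mm planning
  # resample is applied where the curve is used (display, scoring).
  fr <- seq(spec$coronal_fraction, spec$lambdoid_fraction, length.out = 5L)
  sections <- list(coronal = fr[1], virtual_1 = fr[2], virtual_2 = fr[3],
                   virtual_3 = fr[4], lambdoid = fr[5])
  sutures <- lapply(names(sections), function(nm) {
    cur <- mesh_plane_section(surface, "x", sections[[nm]] * ax[1],
                              label = nm)
    if (cur[1, 2] > cur[nrow(cur), 2]) {  # orient left -> right
      cur <- polyline3(cur[rev(seq_len(nrow(cur))), ], label = nm)
    }
    cur
  })
  names(sutures) <- names(sections)
  sagittal <- mesh_plane_section(surface, "y", 0, label = "sagittal")
  if (sagittal[1, 1] < sagittal[nrow(sagittal), 1]) {  # anterior first
    sagittal <- polyline3(sagittal[rev(seq_len(nrow(sagittal))), ],
                          label = "sagittal")
  }
  sutures$sagittal <- sagittal
  sutures <- sutures[c("sagittal", "coronal", "virtual_1", "virtual_2",
                       "virtual_3", "lambdoid")]

  # six anatomical landmarks clustered on the anterior "face" region
  # (around the nasion/orbital rim of a real skull): low elevation, small
  # azimuth about the +x axis
  lm_theta <- c(-0.55, -0.35, -0.15, 0.15, 0.35, 0.55)
  lm_phi <- c(0.28, 0.12, 0.22, 0.22, 0.12, 0.28)
  lm_raw <- ellipsoid_point(ax, lm_theta, lm_phi)
  lm_on <- closest_point_on_surface(surface, lm_raw)$point
  landmarks <- labeled_points(paste0("landmark_", 1:6), lm_on)

  # fiducials: seeded stratified sampling over the vault (one per azimuth
  # stratum, elevation jittered), then snapped to the mesh
  nf <- spec$n_fiducials
  fid_raw <- with_seed(derive_seed(seed, "fiducials"), {
    theta <- (seq_len(nf) - 1) * 2 * pi / nf +
      stats::runif(nf, 0.1, 0.9) * 2 * pi / nf
    phi <- stats::runif(nf, 0.25, 1.25)
    ellipsoid_point(ax, theta, phi)
  })
  fiducials <- labeled_points(paste0("fiducial_", seq_len(nf)),
                              closest_point_on_surface(surface, fid_raw)$point)

  # fixed patient-sensor mounting pose (sensor sits behind the vertex)
  pose <- rigid_transform(rot_z(0.3) %*% rot_x(0.15),
                          c(-0.3 * ax[1], 0, 1.1 * ax[3]))

  structure(list(surface = surface, sutures = sutures,
                 anatomical_landmarks = landmarks, fiducials = fiducials,
                 patient_sensor_pose = pose,
                 spec = spec, seed = as.integer(seed), id = id),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("<phantom_model>", x$id, "-", nrow(x$surface$vertices), "vertices,",
      length(x$sutures), "sutures,", nrow(x$fiducials), "fiducials, seed",
      x$seed, "\n")
  invisible(x)
}

#' Write phantom files
#'
#' Writes the surface (STL or PLY), one CSV per suture curve, landmark and
#' fiducial point sets (FCSV), and a plain-text manifest listing the files,
#' the seed and the generating spec.
#'
#' @param phantom a `phantom_model`.
#' @param dir output directory (created if missing).
#' @param mesh_format `"stl"` or `"ply"`.
#' @return Invisibly, the manifest path.
#' @export
write_phantom <- function(phantom, dir, mesh_format = c("stl", "ply")) {
  mesh_format <- match.arg(mesh_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh_file <- file.path(dir, paste0("surface.", mesh_format))
  write_mesh(phantom$surface, mesh_file)
  curve_files <- vapply(names(phantom$sutures), function(nm) {
    f <- file.path(dir, paste0("suture_", nm, ".csv"))
    write_curve(phantom$sutures[[nm]], f)
    f
  }, character(1))
  lm_file <- file.path(dir, "landmarks.fcsv")
  fid_file <- file.path(dir, "fiducials.fcsv")
  write_points(phantom$anatomical_landmarks, lm_file)
  write_points(phantom$fiducials, fid_file)
  pose_file <- file.path(dir, "patient_sensor_pose.txt")
  write_transform(phantom$patient_sensor_pose, pose_file,
                  from = "CT", to = "PATIENT_SENSOR")
  manifest <- file.path(dir, "phantom_manifest.txt")
  writeLines(c(
    paste("id:", phantom$id),
    paste("seed:", phantom$seed),
    paste("semi_axes_mm:", paste(phantom$spec$semi_axes, collapse = " ")),
    paste("n_fiducials:", phantom$spec$n_fiducials),
    paste("tessellation_level:", phantom$spec$tessellation_level),
    paste("coronal_fraction:", phantom$spec$coronal_fraction),
    paste("lambdoid_fraction:", phantom$spec$lambdoid_fraction),
    paste("surface:", basename(mesh_file)),
    paste("sutures:", paste(basename(curve_files), collapse = " ")),
    paste("landmarks:", basename(lm_file)),
    paste("fiducials:", basename(fid_file)),
    paste("patient_sensor_pose:", basename(pose_file))),
    manifest)
  invisible(manifest)
}

#' Noise specification for simulated digitization and delineation
#'
#' Three noise channels stand in for the error sources of a phantom study:
#' isotropic Gaussian digitization noise of a tracked pointer
#' (`digitization_sigma`), smooth in-tangent-plane wander of a human pen
#' stroke (`delineation_sigma`, correlated along the curve over
#' `delineation_correlation_length`), and an optional constant sideways
#' offset of the stroke (`systematic_offset`).
#'
#' @param digitization_sigma per-axis pointer noise sd, mm (>= 0).
#' @param delineation_sigma marginal sd of the stroke's tangent-plane
#'   displacement, mm (>= 0).
#' @param delineation_correlation_length arc-length correlation scale of
#'   the stroke noise, mm (> 0).
#' @param systematic_offset signed constant offset perpendicular to the
#'   curve within the tangent plane, mm.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(digitization_sigma = 0,
                       delineation_sigma = 0,
                       delineation_correlation_length = 15,
                       systematic_offset = 0) {
  if (digitization_sigma < 0 || delineation_sigma < 0) {
    stop("invalid parameter: sigmas must be >= 0", call. = FALSE)
  }
  if (delineation_correlation_length <= 0) {
    stop("invalid parameter: correlation length must be > 0", call. = FALSE)
  }
  structure(list(digitization_sigma = digitization_sigma,
                 delineation_sigma = delineation_sigma,
                 delineation_correlation_length =
                   delineation_correlation_length,
                 systematic_offset = systematic_offset),
            class = "noise_spec")
}

# Smooth columns of iid N(0,1) draws along arc positions s with a Gaussian
# kernel of scale L, renormalized so the marginal sd stays 1 at each point.
smooth_unit_field <- function(z, s, L) {
  w <- exp(-0.5 * (outer(s, s, "-") / L)^2)
  (w %*% z) / sqrt(rowSums(w^2))
}

#' Simulate a hand-drawn suture
#'
#' Models a participant tracing a displayed suture on the skull: the
#' reference is resampled, each sample is displaced within the local
#' surface tangent plane by a smooth correlated Gaussian field (plus any
#' systematic sideways offset), and the result is re-projected onto the
#' surface. With all noise parameters zero the output is the projected,
#' resampled reference.
#'
#' @param surface the skull `tri_surface`.
#' @param reference the displayed suture, a `polyline3`.
#' @param noise a [noise_spec()]; only the delineation channels are used.
#' @param seed integer seed.
#' @param step resample step in mm.
#' @return The drawn suture as a `polyline3` on the surface.
#' @export
simulate_drawn_suture <- function(surface, reference, noise, seed,
                                  step = 0.25) {
  stopifnot(inherits(surface, "tri_surface"), inherits(noise, "noise_spec"))
  ref <- resample_polyline(project_polyline(surface, reference), step)
  pts <- as_point_matrix(ref)
  n <- nrow(pts)
  cp <- closest_point_on_surface(surface, pts)
  normals <- triangle_normals(surface, cp$triangle)

  # local frame: tangent along the curve, binormal = normal x tangent
  tangents <- rbind(pts[2, ] - pts[1, ],
                    pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
                    pts[n, ] - pts[n - 1, ])
  tangents <- tangents / sqrt(rowSums(tangents^2))
  binorm <- cbind(
    normals[, 2] * tangents[, 3] - normals[, 3] * tangents[, 2],
    normals[, 3] * tangents[, 1] - normals[, 1] * tangents[, 3],
    normals[, 1] * tangents[, 2] - normals[, 2] * tangents[, 1])
  binorm <- binorm / sqrt(rowSums(binorm^2))

  disp <- matrix(0, n, 3L)
  if (noise$delineation_sigma > 0) {
    s <- cum_arc(pts)
    L <- noise$delineation_correlation_length
    z <- with_seed(seed, matrix(stats::rnorm(2L * n), n, 2L))
    f <- smooth_unit_field(z, s, L)
    disp <- noise$delineation_sigma * (tangents * f[, 1] + binorm * f[, 2])
  }
  if (noise$systematic_offset != 0) {
    disp <- disp + noise$systematic_offset * binorm
  }
  drawn <- pts + disp
  polyline3(closest_point_on_surface(surface, drawn)$point,
            label = curve_label(reference))
}
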