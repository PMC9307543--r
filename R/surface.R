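#' Triangulated surfaces
#'
#' A `tri_surface` holds a triangle mesh — typically a CT-derived skull
#' surface — as an N x 3 vertex matrix (mm) and an M x 3 matrix of 1-based
#' vertex indices. Construction validates index ranges, finiteness, and
#' rejects degenerate triangles (area below `1e-12` mm^2). An axis-aligned
#' bounding-box tree is built lazily and cached for closest-point queries.
#'
#' @param vertices N x 3 numeric matrix of vertex coordinates in mm.
#' @param triangles M x 3 integer matrix of 1-based vertex indices.
#' @return A `tri_surface` object.
#' @export
tri_surface <- function(vertices, triangles) {
  vertices <- as_point_matrix(vertices)
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3L) {
    stop("triangles must have 3 columns", call. = FALSE)
  }
  storage.mode(triangles) <- "integer"
  if (nrow(vertices) == 0L || nrow(triangles) == 0L) {
    stop("degenerate input: empty surface", call. = FALSE)
  }
  if (!all(is.finite(vertices))) {
    stop("non-finite vertex coordinates", call. = FALSE)
  }
  if (min(triangles) < 1L || max(triangles) > nrow(vertices)) {
    stop("triangle index out of range", call. = FALSE)
  }
  areas <- triangle_areas(vertices, triangles)
  if (any(areas < 1e-12)) {
    stop("degenerate triangle(s) with area < 1e-12 mm^2: indices ",
         paste(utils::head(which(areas < 1e-12), 5L), collapse = ", "),
         call. = FALSE)
  }
  structure(list(vertices = vertices, triangles = triangles,
                 .cache = new.env(parent = emptyenv())),
            class = "tri_surface")
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  u <- vertices[triangles[, 2], , drop = FALSE] - a
  v <- vertices[triangles[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("<tri_surface>", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

surface_tree <- function(surface) {
  cache <- surface$.cache
  if (is.null(cache$tree)) {
    cache$tree <- .cpp_mesh_tree(surface$vertices, surface$triangles)
  }
  cache$tree
}

#' Outward unit normals of selected triangles
#'
#' Normal orientation follows the triangle winding; the synthetic phantom
#' winds its triangles outward.
#'
#' @param surface a `tri_surface`.
#' @param index triangle indices (default all).
#' @return A length(index) x 3 matrix of unit normals.
#' @export
triangle_normals <- function(surface, index = seq_len(nrow(surface$triangles))) {
  tr <- surface$triangles[index, , drop = FALSE]
  a <- surface$vertices[tr[, 1], , drop = FALSE]
  u <- surface$vertices[tr[, 2], , drop = FALSE] - a
  v <- surface$vertices[tr[, 3], , drop = FALSE] - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n / sqrt(rowSums(n^2))
}

#' Closest points on a triangulated surface
#'
#' For each query point, finds the exact nearest point on the mesh (the
#' "foot point"), classifying against triangle interiors, edges and
#' vertices. Ties between equidistant triangles are broken deterministically
#' by lowest triangle index.
#'
#' @param surface a `tri_surface`.
#' @param points query point(s): length-3 vector or N x 3 matrix (mm).
#' @return A list with `point` (N x 3 foot points), `distance` (mm) and
#'   `triangle` (1-based triangle index of each foot point).
#' @export
closest_point_on_surface <- function(surface, points) {
  stopifnot(inherits(surface, "tri_surface"))
  pts <- as_point_matrix(points)
  if (nrow(pts) == 0L) {
    return(list(point = pts, distance = numeric(0), triangle = integer(0)))
  }
  if (!all(is.finite(pts))) {
    stop("non-finite query coordinates", call. = FALSE)
  }
  .cpp_closest_points(surface_tree(surface), pts)
}

#' Read and write triangle meshes (STL and PLY)
#'
#' STL is read in both ASCII and binary form; on read, duplicate vertices
#' are merged (STL stores each facet's corners independently). PLY support
#' covers ASCII files with `vertex` (x,y,z) and `face` elements. Units are
#' assumed to be mm. Meshes violating the `tri_surface` invariants (bad
#' indices, degenerate triangles) are rejected.
#'
#' @param path file path; extension `.stl` or `.ply` picks the format.
#' @param surface a `tri_surface`.
#' @param binary for STL output, write the binary form (default ASCII).
#' @return `read_mesh()` returns a `tri_surface`; `write_mesh()` returns
#'   `path` invisibly.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unknown mesh format: .", ext, call. = FALSE))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(surface, path, binary = FALSE) {
  stopifnot(inherits(surface, "tri_surface"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(surface, path, binary = binary),
         ply = write_ply(surface, path),
         stop("unknown mesh format: .", ext, call. = FALSE))
  invisible(path)
}

is_binary_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 84L)
  if (length(head) < 84L) return(FALSE)
  ntri <- readBin(head[81:84], "integer", 1L, size = 4L, endian = "little")
  file.size(path) == 84 + 50 * ntri
}

read_stl <- function(path) {
  if (is_binary_stl(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    tri_pts <- matrix(0, 3L * ntri, 3L)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L)  # attribute byte count
      tri_pts[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L,
                                                  byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vx <- grep("^[[:space:]]*vertex", lines, value = TRUE)
    tri_pts <- do.call(rbind, lapply(strsplit(trimws(vx), "[[:space:]]+"),
                                     function(p) as.numeric(p[2:4])))
    if (is.null(tri_pts) || nrow(tri_pts) %% 3L != 0L) {
      stop("malformed ASCII STL", call. = FALSE)
    }
  }
  weld_facets(tri_pts)
}

# Merge per-facet corner soup into shared vertices (exact coordinate match).
weld_facets <- function(tri_pts) {
  key <- paste(tri_pts[, 1], tri_pts[, 2], tri_pts[, 3])
  idx <- match(key, unique(key))
  verts <- tri_pts[!duplicated(key), , drop = FALSE]
  tris <- matrix(idx, ncol = 3L, byrow = TRUE)
  tri_surface(verts, tris)
}

write_stl <- function(surface, path, binary = FALSE) {
  v <- surface$vertices
  tr <- surface$triangles
  n <- triangle_normals(surface)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(n[i, ], t(v[tr[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmt <- function(x) paste(sprintf("%.9g", x), collapse = " ")
    out <- character(7L * nrow(tr) + 2L)
    out[1] <- "solid surface"
    k <- 2L
    for (i in seq_len(nrow(tr))) {
      out[k:(k + 6L)] <- c(
        paste(" facet normal", fmt(n[i, ])),
        "  outer loop",
        paste("   vertex", fmt(v[tr[i, 1], ])),
        paste("   vertex", fmt(v[tr[i, 2], ])),
        paste("   vertex", fmt(v[tr[i, 3], ])),
        "  endloop",
        " endfacet")
      k <- k + 7L
    }
    out[k] <- "endsolid surface"
    writeLines(out, path)
  }
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(trimws(lines[1]), "ply")) {
    stop("not a PLY file", call. = FALSE)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header has no end_header", call. = FALSE)
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format binary", header))) {
    stop("binary PLY is not supported; export as ASCII", call. = FALSE)
  }
  el <- grep("^element", header, value = TRUE)
  counts <- stats::setNames(
    as.integer(vapply(strsplit(el, "[[:space:]]+"), `[`, character(1), 3L)),
    vapply(strsplit(el, "[[:space:]]+"), `[`, character(1), 2L))
  nv <- counts[["vertex"]]
  nf <- counts[["face"]]
  body <- trimws(lines[(end + 1L):length(lines)])
  body <- body[nzchar(body)]
  vparts <- strsplit(body[seq_len(nv)], "[[:space:]]+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(body[nv + seq_len(nf)], "[[:space:]]+")
  tris <- t(vapply(fparts, function(p) {
    if (as.integer(p[1]) != 3L) {
      stop("PLY face is not a triangle", call. = FALSE)
    }
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  tri_surface(verts, tris)
}

write_ply <- function(surface, path) {
  v <- surface$vertices
  tr <- surface$triangles
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nrow(v)),
              "property double x", "property double y", "property double z",
              paste("element face", nrow(tr)),
              "property list uchar int vertex_indices",
              "end_header")
  vlines <- sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
  flines <- sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L)
  writeLines(c(header, vlines, flines), path)
}

#' Section a mesh with an axis-aligned plane
#'
#' Intersects the mesh with the plane `coordinate == value` and chains the
#' per-triangle intersection segments into a single polyline. The returned
#' vertices lie exactly on mesh edges, and every segment lies inside one
#' triangle, so the curve is exactly on the surface and stays there under
#' arc-length resampling. A plane passing exactly through a mesh vertex is
#' nudged by 1e-6 mm to keep the crossing pattern unambiguous.
#'
#' @param surface a `tri_surface`.
#' @param axis `"x"`, `"y"` or `"z"`: the coordinate held fixed.
#' @param value plane position in mm.
#' @param label optional label for the returned curve.
#' @return A `polyline3`. If the section has several connected components,
#'   the longest is returned.
#' @export
mesh_plane_section <- function(surface, axis = c("x", "y", "z"), value,
                               label = NULL) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  v <- surface$vertices
  tr <- surface$triangles
  s <- v[, ai] - value
  guard <- 0L
  while (any(abs(s) < 1e-9) && guard < 5L) {
    value <- value + 1e-6
    s <- v[, ai] - value
    guard <- guard + 1L
  }
  if (any(abs(s) < 1e-9)) {
    stop("plane repeatedly hits mesh vertices; choose another value",
         call. = FALSE)
  }
  sa <- s[tr[, 1]]; sb <- s[tr[, 2]]; sc <- s[tr[, 3]]
  crossed <- (pmin(sa, sb, sc) < 0) & (pmax(sa, sb, sc) > 0)
  if (!any(crossed)) {
    stop("plane does not intersect the mesh", call. = FALSE)
  }
  tidx <- which(crossed)

  # intersection point on edge (i, j); canonical vertex order makes shared
  # edges produce bitwise-identical points in both adjacent triangles
  edge_point <- function(i, j) {
    swap <- i > j
    a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
    t_ <- s[a] / (s[a] - s[b])
    list(point = v[a, , drop = FALSE] * (1 - t_) + v[b, , drop = FALSE] * t_,
         key = paste(a, b))
  }

  seg_p1 <- NULL; seg_p2 <- NULL; key1 <- NULL; key2 <- NULL
  for (t_ in tidx) {
    vi <- tr[t_, ]
    sv <- s[vi]
    cross_edges <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (sv[e[1]] * sv[e[2]] < 0) {
        cross_edges[[length(cross_edges) + 1L]] <- edge_point(vi[e[1]],
                                                              vi[e[2]])
      }
    }
    if (length(cross_edges) == 2L) {
      seg_p1 <- rbind(seg_p1, cross_edges[[1]]$point)
      seg_p2 <- rbind(seg_p2, cross_edges[[2]]$point)
      key1 <- c(key1, cross_edges[[1]]$key)
      key2 <- c(key2, cross_edges[[2]]$key)
    }
  }

  # chain segments into paths via shared edge keys
  nodes <- unique(c(key1, key2))
  i1 <- match(key1, nodes); i2 <- match(key2, nodes)
  coords <- matrix(NA_real_, length(nodes), 3L)
  coords[i1, ] <- seg_p1
  coords[i2, ] <- seg_p2
  adj <- vector("list", length(nodes))
  for (k in seq_along(i1)) {
    adj[[i1[k]]] <- c(adj[[i1[k]]], i2[k])
    adj[[i2[k]]] <- c(adj[[i2[k]]], i1[k])
  }
  deg <- lengths(adj)
  visited <- logical(length(nodes))
  paths <- list()
  for (start in order(deg)) {  # prefer open endpoints (degree 1)
    if (visited[start] || deg[start] == 0L) next
    path <- start
    visited[start] <- TRUE
    repeat {
      nxt <- setdiff(adj[[path[length(path)]]],
                     path[c(max(1L, length(path) - 1L), length(path))])
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0L) break
      path <- c(path, nxt[1])
      visited[nxt[1]] <- TRUE
    }
    paths[[length(paths) + 1L]] <- path
  }
  lens <- vapply(paths, function(p) arc_length(coords[p, , drop = FALSE]),
                 numeric(1))
  best <- coords[paths[[which.max(lens)]], , drop = FALSE]
  polyline3(best, label = label)
}
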