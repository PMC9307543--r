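#' 3-D polylines and suture curves
#'
#' A `polyline3` is an ordered sequence of 3-D points (mm) with positive
#' total arc length; consecutive duplicate points are dropped at
#' construction. A suture curve is a `polyline3` carrying a `label`
#' attribute (e.g. `"coronal"`, `"lambdoid"`, `"virtual_2"`).
#'
#' @param points N x 3 numeric matrix (N >= 2) of ordered coordinates in mm.
#' @param label optional curve label.
#' @return A `polyline3` matrix.
#' @export
polyline3 <- function(points, label = NULL) {
  pts <- as_point_matrix(points)
  if (!all(is.finite(pts))) {
    stop("non-finite polyline coordinates", call. = FALSE)
  }
  if (nrow(pts) >= 2L) {
    seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    pts <- pts[c(TRUE, seg > 0), , drop = FALSE]
  }
  if (nrow(pts) < 2L) {
    stop("a polyline needs at least 2 distinct points", call. = FALSE)
  }
  structure(pts, class = c("polyline3", "matrix"),
            label = if (!is.null(label)) as.character(label) else NULL)
}

#' @rdname polyline3
#' @param x a `polyline3`.
#' @export
curve_label <- function(x) attr(x, "label")

#' @export
print.polyline3 <- function(x, ...) {
  lab <- curve_label(x)
  cat("<polyline3>", if (!is.null(lab)) paste0("'", lab, "' "), nrow(x),
      "points, length", format(arc_length(x), digits = 6), "mm\n")
  invisible(x)
}

#' Arc length of a polyline
#'
#' @param curve a `polyline3` or N x 3 matrix.
#' @return Total length in mm.
#' @export
arc_length <- function(curve) {
  pts <- as_point_matrix(curve)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

# Cumulative arc-length parameter at each polyline vertex (starts at 0).
cum_arc <- function(pts) {
  c(0, cumsum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                              pts[-nrow(pts), , drop = FALSE])^2))))
}

# Point at arc-length parameter s (vectorized), linear interpolation.
point_at_arc <- function(pts, s) {
  cs <- cum_arc(pts)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  seg <- findInterval(s, cs, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(pts) - 1L)
  len <- cs[seg + 1L] - cs[seg]
  w <- ifelse(len > 0, (s - cs[seg]) / len, 0)
  pts[seg, , drop = FALSE] * (1 - w) +
    pts[seg + 1L, , drop = FALSE] * w
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Points are placed every `step` mm along the curve by linear
#' interpolation between the original vertices. Both endpoints are always
#' retained, so the final interval may be shorter than `step`. A curve
#' shorter than one step collapses to its two endpoints.
#'
#' The operation is idempotent: a curve whose interior segments already
#' have chord length `step` (within 1 % of `step`) is returned unchanged.
#' Without this, repeated resampling of a curve lying on a faceted surface
#' lets sample positions drift onto corner-cutting chords and accumulates
#' spurious micrometre-scale deviation; genuinely irregular curves (hand
#' noise, digitization jitter) vary far more than 1 % and are resampled
#' normally.
#'
#' @param curve a `polyline3`.
#' @param step spacing in mm (> 0); 0.25 mm is the planning default.
#' @return A resampled `polyline3` (label preserved).
#' @export
resample_polyline <- function(curve, step = 0.25) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
      step <= 0) {
    stop("invalid parameter: step must be a positive number of mm",
         call. = FALSE)
  }
  pts <- as_point_matrix(curve)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  inner <- seg[-length(seg)]
  if ((length(inner) == 0L || max(abs(inner - step)) <= 1e-2 * step) &&
      seg[length(seg)] <= step * (1 + 1e-2) && nrow(pts) > 2L) {
    return(polyline3(pts, label = curve_label(curve)))
  }
  total <- sum(seg)
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  polyline3(point_at_arc(pts, s), label = curve_label(curve))
}

#' Project a polyline onto a triangulated surface
#'
#' Replaces each curve point by its closest point on the surface, keeping
#' the ordering. Each point is projected independently (no continuity
#' constraint), matching how a tracked pointer digitizes a drawn curve
#' point by point.
#'
#' @param surface a `tri_surface`.
#' @param curve a `polyline3`.
#' @return The projected `polyline3` (label preserved).
#' @export
project_polyline <- function(surface, curve) {
  pts <- as_point_matrix(curve)
  cp <- closest_point_on_surface(surface, pts)
  polyline3(cp$point, label = curve_label(curve))
}

#' Closest point on a polyline, with arc-length parameter
#'
#' For each query point, returns the nearest point on the polyline (over
#' all segments) and its arc-length parameter from the curve start.
#'
#' @param curve a `polyline3`.
#' @param points query points (length-3 vector or N x 3 matrix, mm).
#' @return A list with `point` (N x 3), `arc` (parameter, mm) and
#'   `distance` (mm).
#' @export
closest_point_on_polyline <- function(curve, points) {
  pts <- as_point_matrix(curve)
  q <- as_point_matrix(points)
  cs <- cum_arc(pts)
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  nq <- nrow(q)
  out_pt <- matrix(NA_real_, nq, 3L)
  out_arc <- numeric(nq)
  out_d <- numeric(nq)
  for (i in seq_len(nq)) {
    ap <- sweep(a, 2L, q[i, ], "-")
    t_par <- pmin(pmax(-rowSums(ap * ab) / len2, 0), 1)
    foot <- a + ab * t_par
    d2 <- rowSums(sweep(foot, 2L, q[i, ], "-")^2)
    j <- which.min(d2)
    out_pt[i, ] <- foot[j, ]
    out_arc[i] <- cs[j] + t_par[j] * sqrt(len2[j])
    out_d[i] <- sqrt(d2[j])
  }
  list(point = out_pt, arc = out_arc, distance = out_d)
}

# Clip a polyline to the arc-length interval [s0, s1].
clip_polyline <- function(curve, s0, s1) {
  pts <- as_point_matrix(curve)
  cs <- cum_arc(pts)
  inner <- cs > s0 & cs < s1
  out <- rbind(point_at_arc(pts, s0),
               pts[inner, , drop = FALSE],
               point_at_arc(pts, s1))
  polyline3(out, label = curve_label(curve))
}

#' Read and write suture curves as CSV
#'
#' One file per curve: a first line `# label = <name>` followed by a
#' `x,y,z` header and one point per row (mm).
#'
#' @param curve a `polyline3`.
#' @param path file path (`.csv`).
#' @return `read_curve()` returns a `polyline3`; `write_curve()` returns
#'   `path` invisibly.
#' @export
write_curve <- function(curve, path) {
  pts <- as_point_matrix(curve)
  lab <- curve_label(curve)
  writeLines(c(paste("# label =", if (is.null(lab)) "" else lab),
               "x,y,z",
               sprintf("%.17g,%.17g,%.17g", pts[, 1], pts[, 2], pts[, 3])),
             path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lab <- NULL
  lab_line <- grep("^#\\s*label\\s*=", lines, value = TRUE)
  if (length(lab_line) > 0L) {
    lab <- trimws(sub("^#\\s*label\\s*=", "", lab_line[1]))
    if (!nzchar(lab)) lab <- NULL
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (tolower(trimws(body[1])) == "x,y,z") body <- body[-1L]
  pts <- do.call(rbind, lapply(strsplit(body, ","), function(p)
    as.numeric(p[1:3])))
  polyline3(pts, label = lab)
}
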