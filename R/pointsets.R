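#' Labeled 3-D point sets
#'
#' Anatomical landmarks, fiducial-marker centers and divot calibration
#' points are ordered, uniquely labeled 3-D points in millimetres. A
#' `labeled_points` object is a data frame with columns `label`, `x`, `y`,
#' `z`.
#'
#' @param label character vector of unique labels.
#' @param points N x 3 numeric matrix of coordinates (mm).
#' @return A `labeled_points` data frame.
#' @export
labeled_points <- function(label, points) {
  points <- as_point_matrix(points)
  label <- as.character(label)
  if (length(label) != nrow(points)) {
    stop("label count must match point count", call. = FALSE)
  }
  if (anyDuplicated(label)) {
    stop("labels must be unique", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("non-finite point coordinates", call. = FALSE)
  }
  structure(
    data.frame(label = label, x = points[, 1], y = points[, 2],
               z = points[, 3], stringsAsFactors = FALSE),
    class = c("labeled_points", "data.frame"))
}

#' @rdname labeled_points
#' @param ps a `labeled_points` object.
#' @export
point_matrix <- function(ps) {
  m <- as.matrix(ps[, c("x", "y", "z")])
  rownames(m) <- ps$label
  m
}

#' Match two labeled point sets by label
#'
#' Reorders `b` to the label order of `a`; both must contain exactly the
#' same labels.
#'
#' @param a,b `labeled_points` objects.
#' @return `b` reordered to `a`'s labels.
#' @keywords internal
match_labels <- function(a, b) {
  if (!setequal(a$label, b$label) || nrow(a) != nrow(b)) {
    stop("degenerate input: point sets do not share the same labels",
         call. = FALSE)
  }
  b[match(a$label, b$label), , drop = FALSE]
}

#' Read and write point sets as CSV or Slicer FCSV
#'
#' Plain CSV holds a header `label,x,y,z` with coordinates in mm. FCSV is
#' the 3D Slicer markups fiducial format; its `# CoordinateSystem` header
#' is honored on read: RAS coordinates are converted to the package's
#' internal LPS convention (x and y negated), LPS is taken as-is. Written
#' FCSV always declares LPS.
#'
#' @param ps a `labeled_points` object.
#' @param path file path; the extension (`.csv` or `.fcsv`) picks the format.
#' @return `read_points()` returns a `labeled_points`; writers return
#'   `path` invisibly.
#' @export
write_points <- function(ps, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "fcsv") {
    header <- c(
      "# Markups fiducial file version = 4.11",
      "# CoordinateSystem = LPS",
      "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
    rows <- sprintf("%s,%.10g,%.10g,%.10g,0,0,0,1,1,1,0,%s,,",
                    seq_len(nrow(ps)), ps$x, ps$y, ps$z, ps$label)
    writeLines(c(header, rows), path)
  } else if (ext == "csv") {
    utils::write.csv(as.data.frame(unclass(ps))[, c("label", "x", "y", "z")],
                     path, row.names = FALSE, quote = FALSE)
  } else {
    stop("unknown point-set format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "fcsv") {
    lines <- readLines(path, warn = FALSE)
    cs_line <- grep("CoordinateSystem", lines, value = TRUE)
    ras <- length(cs_line) > 0L &&
      grepl("RAS|= *0", cs_line[1])  # legacy files encode RAS as 0
    rows <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(rows, ",")
    lab <- vapply(parts, function(p) p[12], character(1))
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (ras) xyz[, 1:2] <- -xyz[, 1:2]
    labeled_points(lab, xyz)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("point CSV must have columns label,x,y,z", call. = FALSE)
    }
    labeled_points(df$label, as.matrix(df[, c("x", "y", "z")]))
  } else {
    stop("unknown point-set format: .", ext, call. = FALSE)
  }
}

#' Perturb a labeled point set with digitization noise
#'
#' Adds independent zero-mean Gaussian offsets (standard deviation `sigma`
#' per axis, mm) to every point, modelling tracked-pointer digitization
#' error. Labels are preserved; the output is bit-reproducible given `seed`.
#'
#' @param ps a `labeled_points` object.
#' @param sigma per-axis noise standard deviation in mm (>= 0).
#' @param seed integer seed.
#' @return A perturbed `labeled_points`.
#' @export
perturb_points <- function(ps, sigma, seed) {
  stopifnot(inherits(ps, "labeled_points"), sigma >= 0)
  if (sigma == 0) return(ps)
  m <- point_matrix(ps)
  noise <- with_seed(seed, matrix(stats::rnorm(3L * nrow(m), sd = sigma),
                                  ncol = 3L))
  labeled_points(ps$label, m + noise)
}
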