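#' Named coordinate-frame graphs
#'
#' Tracked navigation systems relate several coordinate frames: the
#' electromagnetic tracker (`EMTS`), the sensor attached to a QR marker
#' (`QR_SENSOR`), the QR marker itself (`QR_MARKER`), the head-mounted
#' display (`HMD`), the patient-attached sensor (`PATIENT_SENSOR`), the CT
#' image frame (`CT`) and an optical tracker used for evaluation (`OTS`).
#' A `frame_graph` stores rigid transforms as directed edges between named
#' frames and resolves the chained mapping between any two connected frames,
#' inverting edges traversed backwards.
#'
#' @param frames character vector of frame names. The canonical tracker
#'   frames above are always present; extra frames may be added here or
#'   implicitly by [add_frame_edge()].
#' @return A `frame_graph` object.
#' @examples
#' g <- frame_graph()
#' g <- add_frame_edge(g, "EMTS", "QR_SENSOR", rigid_transform(rot_z(0.3), c(1, 2, 3)))
#' g <- add_frame_edge(g, "QR_SENSOR", "QR_MARKER", rigid_transform(rot_x(0.1), c(0, 5, 0)))
#' resolve_frame_path(g, "EMTS", "QR_MARKER")
#' @export
frame_graph <- function(frames = character(0)) {
  base_frames <- c("EMTS", "QR_SENSOR", "QR_MARKER", "HMD",
                   "PATIENT_SENSOR", "CT", "OTS")
  structure(
    list(frames = union(base_frames, as.character(frames)),
         edges = list()),
    class = "frame_graph")
}

#' @export
print.frame_graph <- function(x, ...) {
  cat("<frame_graph>", length(x$frames), "frames,",
      length(x$edges), "edges\n")
  for (nm in names(x$edges)) cat("  ", sub("->", " -> ", nm, fixed = TRUE), "\n")
  invisible(x)
}

edge_key <- function(from, to) paste0(from, "->", to)

#' Add a transform edge between two frames
#'
#' At most one edge may exist per ordered frame pair; re-adding replaces it
#' (and its implicit reverse). Unknown frame names are added to the graph.
#'
#' @param graph a `frame_graph`.
#' @param from,to frame names.
#' @param transform the `rigid_transform` mapping coordinates expressed in
#'   `from` to coordinates expressed in `to`.
#' @return The updated `frame_graph`.
#' @export
add_frame_edge <- function(graph, from, to, transform) {
  stopifnot(inherits(graph, "frame_graph"), is_rigid_transform(transform))
  from <- as.character(from); to <- as.character(to)
  if (identical(from, to)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  graph$frames <- union(graph$frames, c(from, to))
  graph$edges[[edge_key(from, to)]] <-
    list(from = from, to = to, transform = transform)
  graph
}

#' Resolve the rigid transform between two frames
#'
#' Finds a path from `source` to `target` by breadth-first search over the
#' edge set, traversing stored edges forwards and their inverses backwards,
#' and returns the composed transform. When several distinct paths exist,
#' they are all resolved and checked for mutual consistency on a probe
#' point set; disagreement beyond `tol` (mm) signals contradictory
#' calibrations and raises an error rather than silently picking one path.
#'
#' @param graph a `frame_graph`.
#' @param source,target frame names present in the graph.
#' @param tol consistency tolerance in mm for multi-path agreement.
#' @return The `rigid_transform` mapping `source` coordinates to `target`
#'   coordinates; the identity when `source == target`.
#' @export
resolve_frame_path <- function(graph, source, target, tol = 1e-6) {
  stopifnot(inherits(graph, "frame_graph"))
  source <- as.character(source); target <- as.character(target)
  missing <- setdiff(c(source, target), graph$frames)
  if (length(missing) > 0L) {
    stop("unknown frame(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (identical(source, target)) return(rt_identity())

  # adjacency: neighbor frame -> transform taking current frame to neighbor
  adj <- list()
  for (e in graph$edges) {
    adj[[e$from]] <- c(adj[[e$from]],
                       list(list(to = e$to, transform = e$transform)))
    adj[[e$to]] <- c(adj[[e$to]],
                     list(list(to = e$from, transform = invert(e$transform))))
  }

  paths <- bfs_paths(adj, source, target)
  if (length(paths) == 0L) {
    stop("unreachable frame: no transform path from '", source,
         "' to '", target, "'", call. = FALSE)
  }
  transforms <- lapply(paths, function(steps) {
    acc <- rt_identity()
    for (step in steps) acc <- compose(acc, step)
    acc
  })
  if (length(transforms) > 1L) {
    probe <- rbind(c(0, 0, 0), diag(3))  # origin + unit axes
    ref <- transform_points(transforms[[1]], probe)
    for (alt in transforms[-1]) {
      dev <- max(sqrt(rowSums((transform_points(alt, probe) - ref)^2)))
      if (dev > tol) {
        stop("inconsistent frame graph: two paths from '", source, "' to '",
             target, "' disagree by ", format(dev), " mm on a unit probe",
             call. = FALSE)
      }
    }
  }
  transforms[[1]]
}

# All simple paths found by BFS layer order (shortest first); each path is a
# list of edge transforms, source to target. Enumerating simple paths is
# exponential in general but frame graphs have a handful of edges.
bfs_paths <- function(adj, source, target, max_paths = 16L) {
  found <- list()
  queue <- list(list(frame = source, visited = source, steps = list()))
  while (length(queue) > 0L && length(found) < max_paths) {
    node <- queue[[1]]; queue <- queue[-1]
    for (nb in adj[[node$frame]]) {
      if (nb$to %in% node$visited) next
      steps <- c(node$steps, list(nb$transform))
      if (identical(nb$to, target)) {
        found <- c(found, list(steps))
      } else {
        queue <- c(queue, list(list(frame = nb$to,
                                    visited = c(node$visited, nb$to),
                                    steps = steps)))
      }
    }
  }
  found
}
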