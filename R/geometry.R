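# Planimetric and polyline geometry underlying all morphometric quantities.
#
# Conventions:
#   * planar contours are n x 2 matrices of (x, y) in micrometres, image y-axis
#     pointing down; areas are absolute values so orientation never flips signs;
#   * a stack of traced sections is converted to volumes/areas by the rectangle
#     rule: each traced section contributes (planar quantity) x section thickness,
#     the convention of serial-section reconstruction software;
#   * section k sits at z = k * thickness, section 0 at z = 0.

as_xy <- function(points, what = "contour") {
  m <- as.matrix(points)
  if (!is.numeric(m) || ncol(m) < 2L) {
    stop_geometry(sprintf("%s points must be a numeric matrix with >= 2 columns", what))
  }
  if (anyNA(m) || any(!is.finite(m))) stop_geometry(sprintf("%s has non-finite coordinates", what))
  m[, 1:2, drop = FALSE]
}

# drop an explicitly repeated closing vertex
strip_closing_vertex <- function(pts) {
  n <- nrow(pts)
  if (n >= 2L && all(pts[1L, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  pts
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Convex polygons are accepted by a fast turning-angle test; non-convex ones
#' fall back to an all-pairs proper segment intersection test.
#'
#' @param points n x 2 numeric matrix of polygon vertices (closing vertex
#'   optional).
#' @return `TRUE` for a simple polygon, `FALSE` otherwise.
#' @export
is_simple_polygon <- function(points) {
  pts <- strip_closing_vertex(as_xy(points))
  n <- nrow(pts)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  e <- pts[nxt, , drop = FALSE] - pts
  if (any(rowSums(e * e) == 0)) return(FALSE)  # repeated vertex
  # convex fast path: all cross products one sign and total turning +-2*pi
  cr <- e[, 1] * e[nxt, 2] - e[, 2] * e[nxt, 1]
  dot <- rowSums(e * e[nxt, , drop = FALSE])
  turn <- sum(atan2(cr, dot))
  if ((all(cr >= 0) || all(cr <= 0)) && abs(abs(turn) - 2 * pi) < 1e-6) return(TRUE)
  # general O(n^2) proper-intersection test over non-adjacent edge pairs
  a1 <- pts; a2 <- pts[nxt, , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- setdiff(seq.int(i + 2L, n), if (i == 1L) n else integer())
    if (!length(j)) next
    if (any(segments_properly_intersect(a1[i, ], a2[i, ], a1[j, , drop = FALSE], a2[j, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

# vectorized proper intersection of segment (p1,p2) against segments (q1,q2) rows
segments_properly_intersect <- function(p1, p2, q1, q2) {
  r <- p2 - p1
  o1 <- r[1] * (q1[, 2] - p1[2]) - r[2] * (q1[, 1] - p1[1])
  o2 <- r[1] * (q2[, 2] - p1[2]) - r[2] * (q2[, 1] - p1[1])
  s1 <- q2[, 1] - q1[, 1]
  s2 <- q2[, 2] - q1[, 2]
  o3 <- s1 * (p1[2] - q1[, 2]) - s2 * (p1[1] - q1[, 1])
  o4 <- s1 * (p2[2] - q1[, 2]) - s2 * (p2[1] - q1[, 1])
  o1 * o2 < 0 & o3 * o4 < 0
}

#' Area of a closed planar contour
#'
#' Shoelace (planimeter) formula with absolute value, so traced orientation is
#' irrelevant.
#'
#' @param points n x 2 matrix of vertices in micrometres.
#' @param check if `TRUE` (default), reject self-intersecting contours.
#' @return area in square micrometres.
#' @export
contour_area <- function(points, check = TRUE) {
  pts <- strip_closing_vertex(as_xy(points))
  if (nrow(pts) < 3L) stop_geometry("a closed contour needs at least 3 distinct points")
  if (check && !is_simple_polygon(pts)) stop_geometry("self-intersecting contour")
  x <- pts[, 1]; y <- pts[, 2]
  i2 <- c(2:nrow(pts), 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Perimeter of a closed contour
#' @inheritParams contour_area
#' @return perimeter in micrometres.
#' @export
contour_perimeter <- function(points) {
  pts <- strip_closing_vertex(as_xy(points))
  if (nrow(pts) < 3L) stop_geometry("a closed contour needs at least 3 distinct points")
  d <- pts[c(2:nrow(pts), 1L), , drop = FALSE] - pts
  sum(sqrt(rowSums(d * d)))
}

#' Area-weighted centroid of a closed contour
#' @inheritParams contour_area
#' @return length-2 numeric (x, y) in micrometres.
#' @export
contour_centroid <- function(points) {
  pts <- strip_closing_vertex(as_xy(points))
  if (nrow(pts) < 3L) stop_geometry("a closed contour needs at least 3 distinct points")
  x <- pts[, 1]; y <- pts[, 2]
  i2 <- c(2:nrow(pts), 1L)
  w <- x * y[i2] - x[i2] * y
  a <- sum(w) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[i2]) * w), sum((y + y[i2]) * w)) / (6 * a)
}

#' Volume of a traced object from its serial contours
#'
#' Rectangle rule: each traced section contributes its contour area times the
#' section thickness. Multiple contours of the object in one section are summed.
#'
#' @param contours list of closed-contour point matrices (micrometres).
#' @param section_thickness section thickness in micrometres.
#' @param check passed to [contour_area()].
#' @return volume in cubic micrometres.
#' @export
object_volume <- function(contours, section_thickness, check = TRUE) {
  if (!length(contours)) stop_geometry("object has no closed contours")
  if (section_thickness <= 0) stop_geometry("section thickness must be positive")
  sum(vapply(contours, contour_area, numeric(1), check = check)) * section_thickness
}

#' Surface area of a traced object from its serial contours
#'
#' Lateral surface = sum of contour perimeters times section thickness (the
#' stair-step estimate); with `include_end_caps` the areas of the first and last
#' sections' contours are added.
#'
#' @param contours list of closed-contour matrices, ordered by section.
#' @param section_thickness section thickness in micrometres.
#' @param include_end_caps add the two extremal contour areas (default `TRUE`).
#' @param check passed to [contour_area()].
#' @return surface area in square micrometres.
#' @export
object_surface_area <- function(contours, section_thickness, include_end_caps = TRUE,
                                check = TRUE) {
  if (!length(contours)) stop_geometry("object has no closed contours")
  if (section_thickness <= 0) stop_geometry("section thickness must be positive")
  lateral <- sum(vapply(contours, contour_perimeter, numeric(1))) * section_thickness
  if (!include_end_caps) return(lateral)
  n <- length(contours)
  lateral + contour_area(contours[[1L]], check = check) +
    contour_area(contours[[n]], check = check)
}

#' Length of an open polyline in 2D or 3D
#'
#' @param points n x 2 or n x 3 numeric matrix (micrometres).
#' @return summed segment length in micrometres.
#' @export
path_length <- function(points) {
  m <- as.matrix(points)
  if (!is.numeric(m) || nrow(m) < 2L) stop_geometry("a path needs at least 2 points")
  if (anyNA(m) || any(!is.finite(m))) stop_geometry("path has non-finite coordinates")
  d <- diff(m)
  seg <- sqrt(rowSums(d * d))
  if (any(seg == 0)) stop_geometry("path has consecutive duplicate points")
  sum(seg)
}

#' PSD area from per-section open traces
#'
#' The postsynaptic density area of one synapse is the section thickness times
#' the summed in-plane length of its PSD traces over consecutive sections.
#' Zero-length traces contribute nothing (with a warning).
#'
#' @param traces list of open-trace point matrices (n x 2, micrometres).
#' @param section_thickness section thickness in micrometres.
#' @return PSD area in square micrometres.
#' @export
psd_area <- function(traces, section_thickness) {
  if (!length(traces)) stop_geometry("synapse has no PSD traces")
  if (section_thickness <= 0) stop_geometry("section thickness must be positive")
  lens <- vapply(traces, function(tr) {
    m <- as_xy(tr, "PSD trace")
    if (nrow(m) < 2L) return(0)
    d <- diff(m)
    sum(sqrt(rowSums(d * d)))
  }, numeric(1))
  if (any(lens == 0)) warning("zero-length PSD trace contributes 0 area", call. = FALSE)
  sum(lens) * section_thickness
}

#' Spine neck length from an explicit neck polyline
#'
#' The neck length is the 3D path length of the traced neck axis from head base
#' to shaft insertion. Zero is permitted for sessile (stubby-like) spines,
#' represented by a degenerate `NULL` trace handled by the caller.
#'
#' @param neck_path n x 3 matrix of neck axis points (micrometres).
#' @return neck length in micrometres.
#' @export
neck_length <- function(neck_path) path_length(neck_path)

#' Spine neck length from head and shaft anchors
#'
#' Deterministic surrogate when no explicit neck trace exists: the distance from
#' the spine head centre to the dendrite axis, minus the head radius and the
#' local shaft radius (head-base to shaft-surface distance), floored at zero.
#'
#' @param head_center length-3 numeric, head centre (micrometres).
#' @param head_radius head radius estimate (micrometres).
#' @param shaft_axis n x 3 matrix, dendrite axis polyline (micrometres).
#' @param shaft_radius local shaft radius (micrometres).
#' @return neck length in micrometres (>= 0).
#' @export
neck_length_from_anchors <- function(head_center, head_radius, shaft_axis, shaft_radius) {
  d <- point_polyline_distance(head_center, shaft_axis)
  max(d - head_radius - shaft_radius, 0)
}

# exact min distance from a 3D point to a 3D polyline
point_polyline_distance <- function(p, polyline) {
  m <- as.matrix(polyline)
  if (nrow(m) == 1L) return(sqrt(sum((m[1L, ] - p)^2)))
  a <- m[-nrow(m), , drop = FALSE]
  b <- m[-1L, , drop = FALSE]
  ab <- b - a
  ap <- sweep(a, 2, p, "-")
  tt <- pmin(pmax(-rowSums(ap * ab) / pmax(rowSums(ab * ab), .Machine$double.xmin), 0), 1)
  close <- a + ab * tt
  sqrt(min(rowSums(sweep(close, 2, p, "-")^2)))
}

#' Dendrite path length from shaft contours
#'
#' The dendrite axis is the 3D polyline through the per-section shaft contour
#' centroids (no smoothing); its path length is the dendritic length used for
#' spine density.
#'
#' @param contours list of closed shaft-contour matrices (micrometres).
#' @param sections integer vector of section indices (0-based), one per contour.
#' @param section_thickness section thickness in micrometres.
#' @return dendritic length in micrometres.
#' @export
dendrite_path_length <- function(contours, sections, section_thickness) {
  if (length(contours) != length(sections)) {
    stop_geometry("contours and sections must have equal length")
  }
  if (length(unique(sections)) < 2L) {
    stop_geometry("dendrite shaft must be traced on at least 2 sections")
  }
  ord <- order(sections)
  cent <- t(vapply(contours[ord], contour_centroid, numeric(2)))
  axis <- cbind(cent, sections[ord] * section_thickness)
  path_length(axis)
}

#' Spine density of a dendrite
#'
#' Number of spines divided by the dendritic path length; multiplying back by
#' the length recovers the integer count exactly.
#'
#' @param n_spines integer spine count (>= 0).
#' @param dendrite_length dendritic length in micrometres (> 0).
#' @return spines per micrometre.
#' @export
spine_density <- function(n_spines, dendrite_length) {
  if (dendrite_length <= 0) stop_geometry("dendrite length must be positive")
  if (n_spines < 0 || n_spines != round(n_spines)) {
    stop_geometry("spine count must be a nonnegative integer")
  }
  n_spines / dendrite_length
}

#' Morphometry configuration
#'
#' @param size_cutoff head-volume cutoff separating small from large spines,
#'   cubic micrometres (default 0.04).
#' @param include_end_caps include end-cap areas in surface area (default
#'   `TRUE`).
#' @param boundary_policy `"exclude_touching"` (default) drops spines whose head
#'   touches the first or last section from statistics; `"include_all"` keeps
#'   them.
#' @return a `morphometry_config` list.
#' @export
morphometry_config <- function(size_cutoff = 0.04, include_end_caps = TRUE,
                               boundary_policy = c("exclude_touching", "include_all")) {
  if (!is.numeric(size_cutoff) || size_cutoff <= 0) {
    stop_validation("size_cutoff must be positive")
  }
  structure(list(size_cutoff = size_cutoff,
                 include_end_caps = isTRUE(include_end_caps),
                 boundary_policy = match.arg(boundary_policy)),
            class = "morphometry_config")
}
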