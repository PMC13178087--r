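#' Planar geometry primitives for traced annotations
#'
#' All traced contours are handled as plain two-column matrices of pixel
#' coordinates (columns `x`, `y`, image convention: y grows downwards). The
#' three primitives below are everything the morphometric ratios need: the
#' absolute shoelace area of a closed contour, the Euclidean length of a
#' trace, and the area of intersection of two closed contours.
#'
#' Coordinates are continuous pixel positions. Because all downstream
#' quantities are ratios (area/area and length/length), no physical
#' calibration (nm/pixel) is required and none is applied.
#'
#' @param xy A two-column numeric matrix (or data frame) of vertex
#'   coordinates, one row per vertex. Polygons are closed implicitly: the
#'   last vertex connects back to the first and must not be repeated.
#' @param id Optional label used in error messages (e.g. the ROI name).
#' @name geometry
NULL

# Coerce vertex input to a 2-column numeric matrix and check finiteness.
as_xy <- function(xy, id = NULL) {
  if (is.data.frame(xy)) {
    cols <- if (all(c("x", "y") %in% names(xy))) c("x", "y") else 1:2
    xy <- as.matrix(xy[, cols])
  }
  if (!is.matrix(xy) || ncol(xy) != 2L || !is.numeric(xy)) {
    abort(paste0("vertex input", label(id), " must be a 2-column numeric matrix"))
  }
  if (!all(is.finite(xy))) {
    abort(paste0("vertex input", label(id), " contains non-finite coordinates"))
  }
  colnames(xy) <- c("x", "y")
  if (nrow(xy) < 2L) return(xy)
  # zero-length edges carry no information and break simplicity checks
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)
  xy[keep, , drop = FALSE]
}

label <- function(id) if (is.null(id)) "" else paste0(" '", id, "'")

# Signed shoelace sum; sign encodes winding direction.
shoelace <- function(xy) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  xs <- c(x[-1L], x[1L])
  ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

cross2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

# TRUE if segment p1-p2 intersects p3-p4 (proper crossing or collinear overlap).
segments_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- cross2(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- cross2(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- cross2(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- cross2(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) {
    return(TRUE)
  }
  on_seg <- function(p, a, b, d) {
    abs(d) <= eps &&
      min(a[1], b[1]) - eps <= p[1] && p[1] <= max(a[1], b[1]) + eps &&
      min(a[2], b[2]) - eps <= p[2] && p[2] <= max(a[2], b[2]) + eps
  }
  on_seg(p1, p3, p4, d1) || on_seg(p2, p3, p4, d2) ||
    on_seg(p3, p1, p2, d3) || on_seg(p4, p1, p2, d4)
}

#' Test whether a closed contour is simple (non-self-intersecting)
#'
#' Pairwise segment test over all non-adjacent edge pairs, O(n^2); adequate
#' for hand-traced contours (tens to hundreds of vertices).
#'
#' @inheritParams geometry
#' @return `TRUE` or `FALSE`.
#' @export
is_simple_polygon <- function(xy) {
  xy <- as_xy(xy)
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n - 2L)) {
    # skip the edge adjacent to i on each side (shared endpoint is legal)
    jmax <- if (i == 1L) n - 1L else n
    if (i + 2L > jmax) next
    for (j in seq(i + 2L, jmax)) {
      if (segments_cross(xy[idx[i], ], xy[idx[i + 1L], ],
                         xy[idx[j], ], xy[idx[j + 1L], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

validate_polygon <- function(xy, id = NULL, check_simple = TRUE) {
  xy <- as_xy(xy, id)
  if (nrow(xy) < 3L) {
    abort(paste0("polygon", label(id), " needs at least 3 distinct vertices"))
  }
  if (abs(shoelace(xy)) < 1e-12 * max(1, max(abs(xy)))^2) {
    abort(paste0("polygon", label(id), " is degenerate (collinear or zero area)"))
  }
  if (check_simple && !is_simple_polygon(xy)) {
    abort(paste0("polygon", label(id), " is self-intersecting"))
  }
  xy
}

#' Absolute area of a simple polygon
#'
#' Shoelace formula with the absolute value taken, so the annotator's winding
#' direction (clockwise or counter-clockwise tracing) does not matter.
#'
#' @inheritParams geometry
#' @param check_simple Verify non-self-intersection (O(n^2)); disable only for
#'   contours known simple by construction.
#' @return Area in squared pixels (strictly positive).
#' @examples
#' polygon_area(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))) # 1
#' @export
polygon_area <- function(xy, id = NULL, check_simple = TRUE) {
  xy <- validate_polygon(xy, id, check_simple)
  abs(shoelace(xy))
}

#' Length of a polyline or polygon perimeter
#'
#' Sum of Euclidean segment lengths. With `closed = TRUE` the closing segment
#' from the last vertex back to the first is included, giving the perimeter.
#'
#' @inheritParams geometry
#' @param closed Include the closing segment (perimeter of a polygon)?
#' @return Length in pixels.
#' @examples
#' path_length(cbind(c(0, 3), c(0, 4))) # 5
#' @export
path_length <- function(xy, closed = FALSE, id = NULL) {
  xy <- as_xy(xy, id)
  if (nrow(xy) < 2L) {
    abort(paste0("polyline", label(id), " needs at least 2 distinct vertices"))
  }
  if (closed) xy <- rbind(xy, xy[1L, ])
  sum(sqrt(rowSums(diff(xy)^2)))
}

# Spatial resolution for integer-scaled clipping: 1e-12 of the coordinate
# magnitude keeps areas exact to ~1e-14 relative without overflowing the
# clipper's 64-bit integers.
clip_eps <- function(...) {
  max(1, vapply(list(...), function(m) max(abs(m)), numeric(1))) * 1e-12
}

#' Area of intersection of two simple polygons
#'
#' Clips `subject` against `clip` (Vatti polygon clipping via
#' \pkg{polyclip}) and returns the total absolute area of the intersection.
#' Used to count only the part of a mitochondrion lying inside the
#' interfibrillar region.
#'
#' @param subject,clip Two-column vertex matrices of simple polygons.
#' @param id Optional label for error messages.
#' @return Intersection area in squared pixels; `0` when disjoint and
#'   `polygon_area(subject)` when `subject` lies inside `clip`.
#' @export
clip_area <- function(subject, clip, id = NULL) {
  subject <- validate_polygon(subject, id)
  clip <- validate_polygon(clip)
  pieces <- polyclip::polyclip(
    list(list(x = subject[, 1L], y = subject[, 2L])),
    list(list(x = clip[, 1L], y = clip[, 2L])),
    op = "intersection", eps = clip_eps(subject, clip)
  )
  if (length(pieces) == 0L) return(0)
  sum(vapply(pieces, function(p) abs(shoelace(cbind(p$x, p$y))), numeric(1)))
}
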