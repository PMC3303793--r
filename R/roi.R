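# ROI polygons: the programmatic replacement for the manual isolation of the
# regenerate from the stump.  Pixel membership is decided by an even-odd
# ray-crossing test at the pixel centre (0-based indices); pixels whose
# centre lies exactly on an edge count as inside.

#' Construct a polygonal region of interest
#'
#' @param vertices numeric matrix with columns `(y, x)` in 0-based pixel
#'   coordinates; at least 3 distinct vertices; the polygon must be simple
#'   (non-self-intersecting).
#' @param sense `"keep_inside"` (default) or `"keep_outside"`.
#' @return an object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, sense = c("keep_inside", "keep_outside")) {
  sense <- match.arg(sense)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L)
    pl_stop("core_io", "vertices must be an n x 2 (y, x) matrix")
  if (nrow(unique(vertices)) < 3L)
    pl_stop("core_io", "degenerate polygon: fewer than 3 distinct vertices")
  if (polygon_self_intersects(vertices))
    pl_stop("core_io", "polygon must be simple (non-self-intersecting)")
  structure(list(vertices = vertices, sense = sense), class = "roi_polygon")
}

# segment-intersection check between all non-adjacent edge pairs
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])  # y1 x1 y2 x2
  cross <- function(oy, ox, ay, ax, by, bx)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- j == i + 1L || (i == 1L && j == n)
      if (adjacent) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# Vectorised even-odd test; py/px are point coordinates, returns logical.
# Points exactly on an edge are reported inside.
point_in_polygon <- function(py, px, vertices, eps = 1e-9) {
  n <- nrow(vertices)
  vy <- vertices[, 1L]; vx <- vertices[, 2L]
  inside <- rep(FALSE, length(py))
  on_edge <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    y1 <- vy[j]; x1 <- vx[j]; y2 <- vy[i]; x2 <- vx[i]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    # on-segment: collinear and within the bounding box
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_edge <- on_edge | (abs(cr) <= eps &
                            px >= pmin(x1, x2) - eps &
                            px <= pmax(x1, x2) + eps &
                            py >= pmin(y1, y2) - eps &
                            py <= pmax(y1, y2) + eps)
    j <- i
  }
  inside | on_edge
}

#' Apply a polygonal ROI to an image
#'
#' Zeroes the pixels on the discarded side of the polygon.  Membership of a
#' pixel is decided by the even-odd rule at its centre; boundary pixels are
#' treated as inside, so `keep_inside` and `keep_outside` of the same
#' polygon partition the nonzero pixels exactly.
#'
#' @param frame 2D matrix `(y, x)` or 3D array `(z, y, x)`; the ROI is
#'   applied plane-wise for 3D input.
#' @param roi a [roi_polygon()].
#' @return the masked frame, same shape as the input.
#' @export
apply_roi <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  d <- dim(frame) %||% pl_stop("core_io", "frame must be a matrix or array")
  is3d <- length(d) == 3L
  ny <- if (is3d) d[2L] else d[1L]
  nx <- if (is3d) d[3L] else d[2L]
  inside <- roi_raster(roi, ny, nx)
  keep <- if (roi$sense == "keep_inside") inside else !inside
  if (is3d) {
    for (z in seq_len(d[1L])) frame[z, , ][!keep] <- 0
  } else {
    frame[!keep] <- 0
  }
  frame
}

# logical (y, x) raster of the polygon interior at pixel centres
roi_raster <- function(roi, ny, nx) {
  py <- rep(seq_len(ny) - 1, times = nx)
  px <- rep(seq_len(nx) - 1, each = ny)
  matrix(point_in_polygon(py, px, roi$vertices), ny, nx)
}

# Rectangle ROI covering the half-plane x >= x_min (or x < x_min), used to
# isolate the regenerate distal to the amputation plane.
halfplane_roi <- function(x_min_px, ny, nx, side = c("distal", "rostral")) {
  side <- match.arg(side)
  v <- if (side == "distal")
    rbind(c(-0.5, x_min_px), c(-0.5, nx), c(ny, nx), c(ny, x_min_px))
  else
    rbind(c(-0.5, -0.5), c(-0.5, x_min_px - 1e-6), c(ny, x_min_px - 1e-6),
          c(ny, -0.5))
  roi_polygon(v, "keep_inside")
}
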