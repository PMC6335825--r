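# Polygon utilities shared by the simulator and the morphometry stage.
# Polygons: n x 2 matrices (x, y) in pixel units, implicit closure.

# Signed area by the shoelace formula (positive for counter-clockwise).
.polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Proper-intersection test between non-adjacent edges; O(n^2), adequate for
# traced outlines (hundreds of vertices).
.polygonIsSimple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  nx <- c(x1[-1], x1[1]); ny <- c(y1[-1], y1[1])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    # skip adjacent edges (shared vertex)
    js <- setdiff(seq(i + 1L, n), c(i, i %% n + 1L, (i - 2L) %% n + 1L))
    if (!length(js)) next
    d1 <- cross(x1[i], y1[i], nx[i], ny[i], x1[js], y1[js])
    d2 <- cross(x1[i], y1[i], nx[i], ny[i], nx[js], ny[js])
    d3 <- cross(x1[js], y1[js], nx[js], ny[js], x1[i], y1[i])
    d4 <- cross(x1[js], y1[js], nx[js], ny[js], nx[i], ny[i])
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

# Even-odd point-in-polygon for an m x 2 point matrix (compiled crossing
# test from mgcv).
.pointsInPolygon <- function(points, poly) {
  bnd <- rbind(poly, poly[1L, , drop = FALSE])
  mgcv::in.out(bnd, points)
}

# Minimal Euclidean distance from each point to the polygon boundary
# (point-to-segment minimum over all edges), in the same units as the
# coordinates.
.pointsToPolygonDistance <- function(points, poly) {
  px <- points[, 1]; py <- points[, 2]
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  d2min <- rep(Inf, length(px))
  for (e in seq_len(n)) {
    ex <- x2[e] - x1[e]; ey <- y2[e] - y1[e]
    len2 <- ex * ex + ey * ey
    if (len2 == 0) {
      d2 <- (px - x1[e])^2 + (py - y1[e])^2
    } else {
      t <- ((px - x1[e]) * ex + (py - y1[e]) * ey) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (x1[e] + t * ex))^2 + (py - (y1[e] + t * ey))^2
    }
    d2min <- pmin(d2min, d2)
  }
  sqrt(d2min)
}

#' Rasterize a traced cell outline into a binary mask
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon under
#' the even-odd rule, matching common raster fill. Pixel (r, c) has its
#' centre at (x, y) = (c - 0.5, r - 0.5), so an axis-aligned square with
#' integer corners (10,10)-(20,20) rasterizes to exactly 100 pixels.
#'
#' @param roi a [CellROI-class] (or bare n x 2 polygon matrix).
#' @param shape integer(2), raster dimensions (rows, cols).
#' @return logical matrix of dimension \code{shape}.
#' @examples
#' roi <- cellROI(cbind(c(10, 20, 20, 10), c(10, 10, 20, 20)), 0.03)
#' sum(polygonToMask(roi, c(30, 30)))  # 100
#' @export
polygonToMask <- function(roi, shape) {
  poly <- if (is(roi, "CellROI")) roiPolygon(roi) else as.matrix(roi)
  if (nrow(poly) < 3L || abs(.polygonArea(poly)) <= 0)
    stop("polygonToMask: degenerate polygon (zero area)")
  shape <- as.integer(shape)
  if (any(poly[, 1] < 0) || any(poly[, 2] < 0) ||
      any(poly[, 1] > shape[2]) || any(poly[, 2] > shape[1]))
    stop("polygonToMask: polygon out of raster bounds")
  mask <- matrix(FALSE, shape[1], shape[2])
  # restrict the point test to the polygon bounding box
  rs <- max(1L, floor(min(poly[, 2]) + 0.5)):min(shape[1], ceiling(max(poly[, 2]) + 0.5))
  cs <- max(1L, floor(min(poly[, 1]) + 0.5)):min(shape[2], ceiling(max(poly[, 1]) + 0.5))
  pts <- cbind(rep(cs - 0.5, each = length(rs)), rep(rs - 0.5, length(cs)))
  inside <- .pointsInPolygon(pts, poly)
  mask[cbind(rep(rs, length(cs)), rep(cs, each = length(rs)))] <- inside
  mask
}
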