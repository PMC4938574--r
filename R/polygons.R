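#' Simple polygon in pixel coordinates
#'
#' Vertices are 0-based pixel-centre coordinates (`x` = column, `y` = row),
#' implicitly closed from the last vertex back to the first. A repeated closing
#' vertex and consecutive duplicate vertices are tolerated and deduplicated on
#' construction. Polygons must be simple (non-self-intersecting).
#'
#' @param vertices two-column numeric matrix (or coercible) of `(x, y)` pairs.
#' @param check validate simplicity (O(n^2) segment test). Disable only for
#'   trusted generator output.
#' @return numeric matrix of class `capillary_polygon` with columns `x`, `y`.
#' @export
polygon_roi <- function(vertices, check = TRUE) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || !is.numeric(v) || anyNA(v))
    stop_capmorph("polygon vertices must be an (n x 2) numeric matrix")
  # drop consecutive duplicates and a repeated closing vertex
  n <- nrow(v)
  if (n > 1L) {
    keep <- c(TRUE, rowSums(abs(v[-1L, , drop = FALSE] -
                                v[-n, , drop = FALSE])) > 0)
    v <- v[keep, , drop = FALSE]
    n <- nrow(v)
    if (n > 1L && all(v[n, ] == v[1L, ])) v <- v[-n, , drop = FALSE]
  }
  if (nrow(v) < 3L)
    stop_capmorph("degenerate polygon: fewer than 3 distinct vertices")
  colnames(v) <- c("x", "y")
  out <- structure(v, class = c("capillary_polygon", "matrix", "array"))
  if (check && !is_simple_polygon(out))
    stop_capmorph("polygon is self-intersecting")
  out
}

# Proper-intersection test between all non-adjacent edge pairs.
is_simple_polygon <- function(poly) {
  v <- unclass(poly); n <- nrow(v)
  nxt <- c(2:n, 1L)
  x1 <- v[, 1]; y1 <- v[, 2]; x2 <- v[nxt, 1]; y2 <- v[nxt, 2]
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  adj <- (j == i + 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (length(i) == 0L) return(TRUE)
  o <- function(ax, ay, bx, by, cx, cy) sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- o(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
  d2 <- o(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- o(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
  d4 <- o(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
  cross <- d1 * d2 < 0 & d3 * d4 < 0
  if (any(cross)) return(FALSE)
  # collinear overlap between non-adjacent edges also breaks simplicity
  col_touch <- (d1 == 0 & on_segment(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])) |
               (d2 == 0 & on_segment(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])) |
               (d3 == 0 & on_segment(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])) |
               (d4 == 0 & on_segment(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i]))
  !any(col_touch)
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) & px <= pmax(ax, bx) & py >= pmin(ay, by) & py <= pmax(ay, by)
}

#' Polygon area by the shoelace formula
#'
#' Orientation-independent (absolute value); result in square micrometres via
#' the per-image calibration.
#'
#' @param poly a [polygon_roi()].
#' @param nm_per_px nanometres per pixel edge.
#' @return area in um^2.
#' @export
polygon_area <- function(poly, nm_per_px) {
  v <- as_polygon(poly)
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v); nxt <- c(2:n, 1L)
  a_px <- abs(sum(x * y[nxt] - x[nxt] * y)) / 2
  a_px * nm_per_px^2 / 1e6
}

#' Polygon perimeter
#'
#' Sum of Euclidean edge lengths including the implicit closing edge, in
#' micrometres.
#'
#' @inheritParams polygon_area
#' @return perimeter in um.
#' @export
polygon_perimeter <- function(poly, nm_per_px) {
  v <- as_polygon(poly)
  n <- nrow(v); nxt <- c(2:n, 1L)
  p_px <- sum(sqrt((v[nxt, 1] - v[, 1])^2 + (v[nxt, 2] - v[, 2])^2))
  p_px * nm_per_px / 1e3
}

as_polygon <- function(poly) {
  if (inherits(poly, "capillary_polygon")) unclass(poly)
  else unclass(polygon_roi(poly, check = FALSE))
}

#' Point-in-polygon test
#'
#' Even-odd rule with the half-open edge convention `ymin <= y < ymax` and
#' `x < x_cross`, so boundary pixels are included on the top/left side only;
#' deterministic and orientation-independent.
#'
#' @param px,py point coordinates (0-based pixel centres), equal length.
#' @param poly a [polygon_roi()].
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  v <- as_polygon(poly); n <- nrow(v)
  inside <- logical(length(px))
  x1 <- v[, 1]; y1 <- v[, 2]
  nxt <- c(2:n, 1L); x2 <- v[nxt, 1]; y2 <- v[nxt, 2]
  for (e in seq_len(n)) {
    ya <- y1[e]; yb <- y2[e]
    if (ya == yb) next
    lo <- min(ya, yb); hi <- max(ya, yb)
    hit <- py >= lo & py < hi
    if (any(hit)) {
      xc <- x1[e] + (py[hit] - ya) * (x2[e] - x1[e]) / (yb - ya)
      inside[hit] <- xor(inside[hit], px[hit] < xc)
    }
  }
  inside
}

# Scanline rasterization: logical mask of pixels whose centres fall inside the
# polygon, for an nrow x ncol raster. Fully vectorized; O(interior pixels).
rasterize_polygon <- function(poly, nr, nc) {
  v <- as_polygon(poly); n <- nrow(v)
  nxt <- c(2:n, 1L)
  x1 <- v[, 1]; y1 <- v[, 2]; x2 <- v[nxt, 1]; y2 <- v[nxt, 2]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  lo <- pmin(y1, y2); hi <- pmax(y1, y2)
  r0 <- pmax(ceiling(lo), 0)                    # first scan row >= lo
  r1 <- pmin(ceiling(hi) - 1, nr - 1L)          # last scan row  <  hi
  cnt <- pmax(r1 - r0 + 1, 0)
  if (sum(cnt) == 0) return(matrix(FALSE, nr, nc))
  edge_id <- rep.int(seq_along(cnt), cnt)
  rows <- sequence(cnt, from = r0, by = 1)
  xc <- x1[edge_id] + (rows - y1[edge_id]) *
    (x2[edge_id] - x1[edge_id]) / (y2[edge_id] - y1[edge_id])
  ord <- order(rows, xc)
  rows <- rows[ord]; xc <- xc[ord]
  # crossings per row are even; pair them into [xlo, xhi) spans
  idx <- seq_along(rows)
  is_lo <- (idx - match(rows, rows)) %% 2 == 0
  xlo <- xc[is_lo]; xhi <- xc[!is_lo]; rsp <- rows[is_lo]
  c0 <- pmax(ceiling(xlo), 0)
  c1 <- pmin(ceiling(xhi) - 1, nc - 1L)
  ncnt <- pmax(c1 - c0 + 1, 0)
  mask <- matrix(FALSE, nr, nc)
  if (sum(ncnt) > 0) {
    span_id <- rep.int(seq_along(ncnt), ncnt)
    cols <- sequence(ncnt, from = c0, by = 1)
    mask[cbind(rsp[span_id] + 1L, cols + 1L)] <- TRUE
  }
  mask
}

# TRUE when every vertex of `inner` lies strictly inside `outer` and no edges
# of the two polygons properly cross.
polygon_inside <- function(inner, outer) {
  vi <- as_polygon(inner)
  all(point_in_polygon(vi[, 1], vi[, 2], outer)) &&
    !polygons_edges_cross(inner, outer)
}

# TRUE when interiors are disjoint (boundaries may touch).
polygon_disjoint <- function(a, b) {
  va <- as_polygon(a); vb <- as_polygon(b)
  if (polygons_edges_cross(a, b)) return(FALSE)
  !any(point_in_polygon(va[, 1], va[, 2], b)) &&
    !any(point_in_polygon(vb[, 1], vb[, 2], a))
}

polygons_edges_cross <- function(a, b) {
  va <- as_polygon(a); vb <- as_polygon(b)
  na <- nrow(va); nb <- nrow(vb)
  an <- c(2:na, 1L); bn <- c(2:nb, 1L)
  ax1 <- rep(va[, 1], each = nb); ay1 <- rep(va[, 2], each = nb)
  ax2 <- rep(va[an, 1], each = nb); ay2 <- rep(va[an, 2], each = nb)
  bx1 <- rep(vb[, 1], times = na); by1 <- rep(vb[, 2], times = na)
  bx2 <- rep(vb[bn, 1], times = na); by2 <- rep(vb[bn, 2], times = na)
  o <- function(ax, ay, bx, by, cx, cy) sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- o(ax1, ay1, ax2, ay2, bx1, by1)
  d2 <- o(ax1, ay1, ax2, ay2, bx2, by2)
  d3 <- o(bx1, by1, bx2, by2, ax1, ay1)
  d4 <- o(bx1, by1, bx2, by2, ax2, ay2)
  any(d1 * d2 < 0 & d3 * d4 < 0)
}
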