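#' Polygon geometry utilities
#'
#' Polygons are closed regions given as a two-column matrix of vertices in
#' pixel coordinates (origin top-left, x rightward, y downward, 0-based).
#' The closing edge from the last vertex back to the first is implicit.
#'
#' @name geometry
#' @keywords internal
NULL

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L || !is.numeric(p)) {
    stop("polygon must be a numeric matrix with >= 3 rows and 2 columns")
  }
  colnames(p) <- c("x", "y")
  p
}

#' Test points for inclusion in a polygon
#'
#' Even-odd ray-casting rule; points on the boundary may fall on either side
#' (half-open convention along edges).
#'
#' @param x,y numeric vectors of point coordinates.
#' @param poly polygon vertex matrix.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  jx <- px[c(n, seq_len(n - 1L))]
  jy <- py[c(n, seq_len(n - 1L))]
  inside <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    crosses <- ((py[i] > y) != (jy[i] > y))
    if (any(crosses)) {
      xint <- px[i] + (y[crosses] - py[i]) * (jx[i] - px[i]) / (jy[i] - py[i])
      inside[crosses] <- xor(inside[crosses], x[crosses] < xint)
    }
  }
  inside
}

# Proper segment intersection test (shared endpoints excluded by the caller).
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Check that a polygon is simple (non-self-intersecting)
#' @keywords internal
is_simple_polygon <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # skip adjacent edges (they share a vertex)
      if (abs(i - j) <= 1L || (i == 1L && j == n)) next
      if (segments_intersect(poly[idx[i, 1], ], poly[idx[i, 2], ],
                             poly[idx[j, 1], ], poly[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel belongs to the mask when its center (col - 1, row - 1 in the
#' 0-based convention) lies inside the polygon.
#'
#' @param poly polygon vertex matrix (0-based pixel coordinates).
#' @param dim image dimension `c(nrow, ncol)`.
#' @return logical matrix of dimension `dim`.
#' @keywords internal
polygon_mask <- function(poly, dim) {
  nr <- dim[1]; nc <- dim[2]
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, times = nc)
  matrix(point_in_polygon(xs, ys, poly), nrow = nr, ncol = nc)
}

polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Intersections of the vertical line x = x0 with the polygon boundary,
# returned as sorted y values (in the polygon's own coordinate frame).
polygon_vline_crossings <- function(poly, x0) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  j <- c(2:n, 1L)
  ys <- numeric(0)
  for (i in seq_len(n)) {
    x1 <- poly[i, 1]; x2 <- poly[j[i], 1]
    if ((x1 <= x0 && x2 > x0) || (x2 <= x0 && x1 > x0)) {
      t <- (x0 - x1) / (x2 - x1)
      ys <- c(ys, poly[i, 2] + t * (poly[j[i], 2] - poly[i, 2]))
    }
  }
  sort(ys)
}
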