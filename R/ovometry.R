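#' Egg morphometry from the outline as a solid of revolution
#'
#' The region of interest drawn around the egg is treated as the silhouette
#' of a solid of revolution: the outline's radius about the long axis is
#' extracted at a set of stations and volume and surface area follow from
#' the standard solid-of-revolution integrals.
#'
#' @name ovometry
NULL

#' Calibrate the image scale from the scale bar
#'
#' @param scale_points 2 x 2 matrix: two pixel coordinates marking a known
#'   physical distance.
#' @param known_mm the physical distance between the two points in mm.
#' @return mm per pixel.
#' @export
calibrate_scale <- function(scale_points, known_mm) {
  scale_points <- as.matrix(scale_points)
  stopifnot(nrow(scale_points) == 2L, ncol(scale_points) == 2L)
  if (known_mm <= 0) stop("known_mm must be positive")
  d <- sqrt(sum((scale_points[1, ] - scale_points[2, ])^2))
  if (d == 0) stop("scale points coincide")
  known_mm / d
}

#' Extract the revolution profile of an egg outline
#'
#' The long axis is the direction through the two most distant boundary
#' points. At each of `n_stations` stations along the axis the outline's two
#' perpendicular half-widths are averaged (the revolved solid ignores
#' bilateral asymmetry of the drawn outline), giving the radius function
#' r(t) with r = 0 at both poles.
#'
#' @param roi simple closed polygon (0-based px).
#' @param mm_per_px image scale from [calibrate_scale()].
#' @param n_stations number of interior stations along the axis.
#' @return an object of class `egg_profile` with fields `t` (station
#'   positions, mm, pole to pole) and `r` (radius at each station, mm).
#' @export
extract_profile <- function(roi, mm_per_px, n_stations = 200) {
  roi <- as_polygon(roi)
  if (mm_per_px <= 0) stop("mm_per_px must be positive")
  if (n_stations < 50) stop("n_stations must be >= 50")
  if (!is_simple_polygon(roi)) stop("geometry error: polygon is self-intersecting")

  # long axis: the two most distant vertices
  n <- nrow(roi)
  dmat <- as.matrix(stats::dist(roi))
  ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  p1 <- roi[ij[1], ]; p2 <- roi[ij[2], ]
  axis_vec <- (p2 - p1) / sqrt(sum((p2 - p1)^2))

  # rotate so the axis is the x direction, p1 at the origin
  rot <- rbind(c(axis_vec[1], axis_vec[2]), c(-axis_vec[2], axis_vec[1]))
  local <- t(rot %*% t(sweep(roi, 2, p1)))
  xmin <- min(local[, 1]); xmax <- max(local[, 1])

  ts <- seq(xmin, xmax, length.out = n_stations + 2L)
  r <- numeric(length(ts))
  for (i in seq_along(ts)) {
    ys <- polygon_vline_crossings(local, ts[i])
    if (length(ys) >= 2) {
      # mean of the two perpendicular half-widths about the axis line y = 0
      r[i] <- (max(ys) - min(ys)) / 2
    } else {
      r[i] <- 0
    }
  }
  r[1] <- 0; r[length(r)] <- 0  # poles
  structure(list(t = (ts - xmin) * mm_per_px, r = r * mm_per_px,
                 axis_endpoints = rbind(p1, p2), mm_per_px = mm_per_px),
            class = "egg_profile")
}

#' Volume, surface area and surface-to-volume ratio of a revolved profile
#'
#' V = pi * integral r(t)^2 dt and S = 2 pi * integral r sqrt(1 + r'^2) dt by
#' the composite trapezoid rule over the stations; r' by central differences,
#' one-sided at the poles.
#'
#' @param profile an `egg_profile` from [extract_profile()].
#' @return an object of class `egg_metrics`: list with `volume_mm3`,
#'   `surface_mm2`, `sv_per_mm`.
#' @export
volume_surface <- function(profile) {
  stopifnot(inherits(profile, "egg_profile"))
  t <- profile$t; r <- profile$r
  if (any(r < 0)) stop("invalid profile: negative radius")
  if (any(diff(t) <= 0)) stop("invalid profile: stations must be strictly increasing")
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  n <- length(t)
  dr <- numeric(n)
  dr[1] <- (r[2] - r[1]) / (t[2] - t[1])
  dr[n] <- (r[n] - r[n - 1]) / (t[n] - t[n - 1])
  dr[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v <- pi * trap(t, r^2)
  s <- 2 * pi * trap(t, r * sqrt(1 + dr^2))
  if (v <= 0 || s <= 0) stop("degenerate profile: non-positive volume or surface")
  structure(list(volume_mm3 = v, surface_mm2 = s, sv_per_mm = s / v),
            class = "egg_metrics")
}

#' @export
print.egg_metrics <- function(x, ...) {
  cat(sprintf("<egg_metrics> V = %.2f mm^3, S = %.2f mm^2, S/V = %.4f mm^-1\n",
              x$volume_mm3, x$surface_mm2, x$sv_per_mm))
  invisible(x)
}
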