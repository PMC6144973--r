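#' VIS-to-UV registration by the Local Weighted Mean transform
#'
#' The VIS and UV exposures of an egg are taken from slightly different
#' positions, so the spot mask segmented in the VIS frame must be carried
#' into the UV frame through a space-variant geometric transformation. The
#' transform is inferred from at least 13 manually marked corresponding
#' points by the Local Weighted Mean (LWM) method: around every control
#' point a second-order bivariate polynomial is fitted through its local
#' neighbourhood, and the mapping at any location is the weight-normalized
#' blend of the nearby polynomials under a radially decreasing kernel that
#' vanishes at each point's influence radius.
#'
#' @name uvalign
NULL

lwm_basis <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

# Fit one direction of the LWM transform. pts_from / pts_to: n x 2 matrices.
lwm_fit_direction <- function(pts_from, pts_to, k_neighbors) {
  n <- nrow(pts_from)
  k <- min(k_neighbors, n)
  D <- as.matrix(stats::dist(pts_from))
  coefs <- array(NA_real_, c(n, 6, 2))
  radius <- numeric(n)
  scale <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])          # self first
    nb <- ord[seq_len(k)]
    radius[i] <- D[i, ord[k]]     # distance to the (k-1)-th nearest neighbour
    if (radius[i] <= 0) stop(sprintf("duplicated VIS control point at index %d", i))
    # local centering/scaling for conditioning
    s <- radius[i]
    scale[i] <- s
    X <- lwm_basis((pts_from[nb, 1] - pts_from[i, 1]) / s,
                   (pts_from[nb, 2] - pts_from[i, 2]) / s)
    for (ax in 1:2) {
      fit <- tryCatch(
        if (k == 6) solve(X, pts_to[nb, ax]) else stats::lsfit(X, pts_to[nb, ax], intercept = FALSE)$coef,
        error = function(e) NULL)
      if (is.null(fit) || anyNA(fit)) {
        stop(sprintf("singular local fit: degenerate neighbourhood around control point %d", i))
      }
      coefs[i, , ax] <- fit
    }
  }
  list(coefs = coefs, radius = radius, scale = scale, centers = pts_from, k = k)
}

# Evaluate one direction at query points (m x 2). Returns mapped coords plus
# the count of locations where no kernel was active (nearest-point fallback).
lwm_eval_direction <- function(dir, xy) {
  m <- nrow(xy); n <- nrow(dir$centers)
  out <- matrix(0, m, 2)
  wsum <- numeric(m)
  # distances query x control
  D2 <- outer(xy[, 1], dir$centers[, 1], "-")^2 + outer(xy[, 2], dir$centers[, 2], "-")^2
  R <- sqrt(D2) / rep(dir$radius, each = m)
  W <- 1 - 3 * R^2 + 2 * R^3
  W[R >= 1] <- 0
  for (i in seq_len(n)) {
    wi <- W[, i]
    act <- wi > 0
    if (!any(act)) next
    Xq <- lwm_basis((xy[act, 1] - dir$centers[i, 1]) / dir$scale[i],
                    (xy[act, 2] - dir$centers[i, 2]) / dir$scale[i])
    out[act, 1] <- out[act, 1] + wi[act] * (Xq %*% dir$coefs[i, , 1])
    out[act, 2] <- out[act, 2] + wi[act] * (Xq %*% dir$coefs[i, , 2])
    wsum <- wsum + wi
  }
  uncovered <- wsum == 0
  if (any(uncovered)) {
    # fall back to the nearest control point's local polynomial
    ni <- max.col(-D2[uncovered, , drop = FALSE])
    for (j in seq_len(sum(uncovered))) {
      i <- ni[j]
      q <- which(uncovered)[j]
      Xq <- lwm_basis((xy[q, 1] - dir$centers[i, 1]) / dir$scale[i],
                      (xy[q, 2] - dir$centers[i, 2]) / dir$scale[i])
      out[q, 1] <- Xq %*% dir$coefs[i, , 1]
      out[q, 2] <- Xq %*% dir$coefs[i, , 2]
      wsum[q] <- 1
    }
  }
  list(xy = out / wsum, n_uncovered = sum(uncovered))
}

#' Fit the Local Weighted Mean transform from control points
#'
#' Requires at least 13 corresponding point pairs (the study's stated
#' minimum for a reliable fit). With the default `k_neighbors = 6` every
#' local polynomial interpolates its neighbourhood exactly, which makes the
#' blended transform exact at all control points; larger neighbourhoods use
#' least squares, trading that exactness for extra smoothing.
#'
#' @param points data.frame or matrix with columns x_vis, y_vis, x_uv, y_uv.
#' @param k_neighbors local neighbourhood size (>= 6).
#' @return an object of class `lwm_transform` holding both the VIS-to-UV
#'   direction and the UV-to-VIS direction (used for inverse-mapping
#'   resampling).
#' @export
fit_lwm <- function(points, k_neighbors = 6) {
  pts <- as.matrix(points)
  if (ncol(pts) != 4) stop("points must have columns x_vis, y_vis, x_uv, y_uv")
  n <- nrow(pts)
  if (n < 13) stop("at least 13 corresponding points are required to fit the transform")
  if (k_neighbors < 6) stop("k_neighbors must be >= 6 (a second-order polynomial has 6 coefficients)")
  vis <- pts[, 1:2, drop = FALSE]; uv <- pts[, 3:4, drop = FALSE]
  if (anyDuplicated(vis)) stop("duplicated VIS control points")
  fwd <- lwm_fit_direction(vis, uv, k_neighbors)
  rev <- lwm_fit_direction(uv, vis, k_neighbors)
  structure(list(points = pts, k_neighbors = k_neighbors,
                 forward = fwd, reverse = rev),
            class = "lwm_transform")
}

#' Map VIS coordinates into the UV frame (or back)
#'
#' @param t an `lwm_transform`.
#' @param xy m x 2 matrix of coordinates.
#' @param direction "forward" (VIS to UV) or "reverse" (UV to VIS).
#' @return m x 2 matrix of mapped coordinates. The number of query locations
#'   outside every kernel (served by the nearest-point fallback) is attached
#'   as attribute `n_uncovered`.
#' @export
predict_lwm <- function(t, xy, direction = c("forward", "reverse")) {
  stopifnot(inherits(t, "lwm_transform"))
  direction <- match.arg(direction)
  xy <- as.matrix(xy)
  res <- lwm_eval_direction(t[[direction]], xy)
  structure(res$xy, n_uncovered = res$n_uncovered)
}

#' @export
print.lwm_transform <- function(x, ...) {
  r <- lwm_residuals(x)
  cat(sprintf("<lwm_transform> %d control points, k = %d, max control residual %.2e px\n",
              nrow(x$points), x$k_neighbors, max(r)))
  invisible(x)
}

#' Residual displacement at the control points
#'
#' @param t an `lwm_transform`.
#' @return numeric vector: |T(vis_i) - uv_i| in px per control point.
#' @export
lwm_residuals <- function(t) {
  mapped <- predict_lwm(t, t$points[, 1:2, drop = FALSE])
  sqrt(rowSums((mapped - t$points[, 3:4, drop = FALSE])^2))
}

#' Transfer a VIS spot mask into the UV frame
#'
#' Inverse mapping with nearest-neighbour assignment: every UV pixel takes
#' the mask value at its mapped VIS location, keeping the mask strictly
#' binary. The RoI footprint is warped alongside the spots.
#'
#' @param mask a `spot_mask` in the VIS frame (from [segment_spots()]).
#' @param t an `lwm_transform` fitted VIS to UV.
#' @param uv_shape dimension `c(nrow, ncol)` of the UV image.
#' @return a `spot_mask` in the UV frame (components relabelled). If part of
#'   the mapped RoI falls outside the UV image a warning reports the clipped
#'   coverage fraction.
#' @export
warp_mask <- function(mask, t, uv_shape = dim(mask$mask)) {
  stopifnot(inherits(mask, "spot_mask"), inherits(t, "lwm_transform"))
  if (mask$frame != "VIS") stop("mask must be in the VIS frame")
  nr <- uv_shape[1]; nc <- uv_shape[2]
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, times = nc)
  src <- predict_lwm(t, cbind(xs, ys), direction = "reverse")
  ci <- round(src[, 1]) + 1L   # 0-based x -> column
  ri <- round(src[, 2]) + 1L
  inside <- ri >= 1 & ri <= nrow(mask$mask) & ci >= 1 & ci <= ncol(mask$mask)
  take <- function(m) {
    v <- rep(FALSE, length(xs))
    v[inside] <- m[cbind(ri[inside], ci[inside])]
    matrix(v, nr, nc)
  }
  uv_spots <- take(mask$mask)
  uv_roi <- take(mask$roi_mask)

  # coverage check: forward-map a sample of the VIS RoI and measure clipping
  roi_px <- which(mask$roi_mask)
  rr <- ((roi_px - 1L) %% nrow(mask$mask))
  cc <- ((roi_px - 1L) %/% nrow(mask$mask))
  sub <- seq(1, length(roi_px), length.out = min(500, length(roi_px)))
  mapped <- predict_lwm(t, cbind(cc[sub], rr[sub]))
  out_frac <- mean(mapped[, 1] < 0 | mapped[, 1] > nc - 1 | mapped[, 2] < 0 | mapped[, 2] > nr - 1)
  if (out_frac > 0) {
    warning(sprintf("mapped RoI extends outside the UV frame: %.1f%% clipped", 100 * out_frac))
  }

  labels <- label_components(uv_spots)
  areas_px <- if (max(labels) > 0) as.numeric(tabulate(labels[labels > 0])) else numeric(0)
  structure(list(mask = uv_spots, labels = labels, areas_px = areas_px,
                 roi_mask = uv_roi, roi = NULL, frame = "UV"),
            class = "spot_mask")
}

#' Spot and background reflectance in the UV band
#'
#' Means of the UV image's red band over the warped spot mask and over the
#' warped RoI minus spots. Because the nearest-neighbour resampling of the
#' mask is uncertain along region boundaries -- and the transform itself is
#' least constrained near the RoI rim, beyond the control-point hull -- the
#' measurement sets are eroded before averaging: the spot set by one pixel,
#' the (plentiful) background set by three. Erosion falls back to the
#' uneroded set if it empties it; geometry reports always use the uneroded
#' mask.
#'
#' @param refl_uv UV [reflectance_image()].
#' @param warped_mask `spot_mask` in the UV frame.
#' @return list with `S_UV` (NA when the warped mask is empty) and `B_UV`.
#' @export
uv_measure <- function(refl_uv, warped_mask) {
  stopifnot(inherits(refl_uv, "reflectance_image"), inherits(warped_mask, "spot_mask"))
  if (warped_mask$frame != "UV") stop("mask must be in the UV frame")
  band <- if ("UV" %in% names(refl_uv$bands)) "UV" else names(refl_uv$bands)[1]
  erode <- function(m, depth) {
    for (i in seq_len(depth)) {
      out <- m
      for (dr in -1:1) for (dc in -1:1) out <- out & shift_mat(m, dr, dc, FALSE)
      if (!any(out)) return(m)
      m <- out
    }
    m
  }
  bg <- warped_mask$roi_mask & !warped_mask$mask
  b_uv <- band_mean(refl_uv, band, erode(bg, 3))
  s_uv <- if (any(warped_mask$mask)) band_mean(refl_uv, band, erode(warped_mask$mask, 1)) else NA_real_
  list(S_UV = s_uv, B_UV = b_uv)
}
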