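#' Maculation segmentation and per-egg trait report
#'
#' Spots are segmented inside the egg RoI of a VIS reflectance image by a
#' local-mean adaptive threshold (a pixel is a spot candidate when it lies at
#' least `offset_pp` percentage points below the mean reflectance of its
#' surrounding window), followed by binary opening and 8-connected component
#' labelling with a minimum area.
#'
#' @name spotscan
NULL

# Local mean over a (2h+1)-square window via an integral image, computed on
# an RoI-masked image so pixels outside the RoI never enter the mean.
local_mean <- function(img, roi_mask, window_px) {
  h <- floor(window_px / 2)
  nr <- nrow(img); nc <- ncol(img)
  v <- img; v[!roi_mask] <- 0
  w <- matrix(as.numeric(roi_mask), nr, nc)
  pad_cum <- function(m) {
    cm <- apply(m, 2, cumsum)
    t(apply(cm, 1, cumsum))
  }
  Sv <- pad_cum(v); Sw <- pad_cum(w)
  boxsum <- function(S) {
    r1 <- pmax(row(img) - h - 1, 0); r2 <- pmin(row(img) + h, nr)
    c1 <- pmax(col(img) - h - 1, 0); c2 <- pmin(col(img) + h, nc)
    at <- function(r, c) {
      out <- matrix(0, nr, nc)
      ok <- r > 0 & c > 0
      out[ok] <- S[cbind(r[ok], c[ok])]
      out
    }
    at(r2, c2) - at(r1, c2) - at(r2, c1) + at(r1, c1)
  }
  num <- boxsum(Sv); den <- boxsum(Sw)
  out <- num / pmax(den, 1)
  out[den == 0] <- NA_real_
  out
}

# 3x3 binary erosion / dilation by shifting
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

binary_open <- function(m) {
  er <- m
  for (dr in -1:1) for (dc in -1:1) er <- er & shift_mat(m, dr, dc, FALSE)
  di <- er
  for (dr in -1:1) for (dc in -1:1) di <- di | shift_mat(er, dr, dc, FALSE)
  di
}

# 8-connected component labelling through the pixel adjacency graph
label_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask)
  id <- seq_along(idx)
  pos <- integer(length(mask)); pos[idx] <- id
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[j]
    if (any(hit)) edges <- c(edges, rbind(id[ok][hit], pos[j[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel in raster order of first appearance so labels are contiguous from 1
  first <- tapply(seq_along(idx), comp, min)
  rank <- rank(first)
  lab[idx] <- as.integer(rank[comp])
  lab
}

#' Segment maculation spots inside the RoI
#'
#' @param refl_vis a VIS [reflectance_image()].
#' @param roi closed polygon delimiting the measurable egg area (0-based px).
#' @param params list: `window_px` local-mean window side (odd), `offset_pp`
#'   threshold offset below the local mean in percentage points,
#'   `min_spot_px` minimum component area in px.
#' @return an object of class `spot_mask`: list with `mask` (logical, VIS
#'   frame), `labels` (integer matrix, components labelled 1..n in raster
#'   order), `areas_px`, `roi_mask`, `frame = "VIS"`.
#' @export
segment_spots <- function(refl_vis, roi,
                          params = list(window_px = 31, offset_pp = 5, min_spot_px = 9)) {
  stopifnot(inherits(refl_vis, "reflectance_image"))
  if (any(unlist(params) <= 0)) stop("segmentation parameters must be positive")
  d <- dim(refl_vis)
  roi <- as_polygon(roi)
  if (any(roi[, 1] < 0) || any(roi[, 2] < 0) || any(roi[, 1] > d[2] - 1) || any(roi[, 2] > d[1] - 1)) {
    stop("geometry error: RoI lies outside the image")
  }
  roi_mask <- polygon_mask(roi, d)
  if (sum(roi_mask) < 100) stop("RoI must cover at least 100 px")

  # across-band mean VIS reflectance drives the threshold
  vis <- Reduce(`+`, refl_vis$bands) / length(refl_vis$bands)
  lm <- local_mean(vis, roi_mask, params$window_px)
  cand <- roi_mask & !is.na(lm) & (vis <= lm - params$offset_pp)
  cand <- binary_open(cand) & roi_mask
  labels <- label_components(cand)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0])
    keep <- which(areas >= params$min_spot_px)
    labels[!(labels %in% keep)] <- 0L
    # recompact labels
    if (length(keep) > 0) {
      remap <- integer(max(labels))
      remap[sort(keep)] <- seq_along(keep)
      labels[labels > 0] <- remap[labels[labels > 0]]
    }
  }
  mask <- labels > 0
  areas_px <- if (max(labels) > 0) as.numeric(tabulate(labels[labels > 0])) else numeric(0)
  structure(list(mask = mask, labels = labels, areas_px = areas_px,
                 roi_mask = roi_mask, roi = roi, frame = "VIS"),
            class = "spot_mask")
}

#' @export
print.spot_mask <- function(x, ...) {
  cat(sprintf("<spot_mask> frame %s, %d spots, %d / %d px in RoI\n", x$frame,
              length(x$areas_px), sum(x$mask), sum(x$roi_mask)))
  invisible(x)
}

#' Summarize spot geometry and reflectance into the per-egg trait report
#'
#' Background (B) statistics are computed over RoI minus the spot mask, spot
#' (S) statistics over the mask. VIS reflectances are reported per band and
#' as the unweighted across-band mean of the R, G and B means; UV uses the
#' UV image's red band. For a spotless egg the S_* fields carry NA (the
#' missing-value sentinel, written as a blank CSV field).
#'
#' @param refl_vis VIS [reflectance_image()].
#' @param refl_uv UV [reflectance_image()] aligned to the mask frame, or NULL
#'   when no UV measurement is available.
#' @param mask a `spot_mask` aligned to `refl_vis`.
#' @param roi the RoI polygon (same one used for segmentation).
#' @param mm_per_px image scale.
#' @param egg_id identifier carried into the report.
#' @return an object of class `spot_report` (a one-row list of the Table-1
#'   trait variables plus per-band values and geometry).
#' @export
summarize_spots <- function(refl_vis, refl_uv, mask, roi, mm_per_px, egg_id = "egg") {
  stopifnot(inherits(mask, "spot_mask"), inherits(refl_vis, "reflectance_image"))
  if (!identical(dim(refl_vis), dim(mask$mask))) stop("mask is not aligned to the VIS image frame")
  if (mm_per_px <= 0) stop("mm_per_px must be positive")
  roi_mask <- mask$roi_mask
  bg <- roi_mask & !mask$mask
  if (!any(bg)) stop("degenerate background: RoI is fully spotted")
  n_spots <- length(mask$areas_px)

  b_band <- vapply(c("R", "G", "B"), function(b) band_mean(refl_vis, b, bg), 0)
  s_band <- if (n_spots > 0) {
    vapply(c("R", "G", "B"), function(b) band_mean(refl_vis, b, mask$mask), 0)
  } else c(R = NA_real_, G = NA_real_, B = NA_real_)

  if (!is.null(refl_uv)) {
    uvband <- if ("UV" %in% names(refl_uv$bands)) "UV" else names(refl_uv$bands)[1]
    b_uv <- band_mean(refl_uv, uvband, bg)
    s_uv <- if (n_spots > 0) band_mean(refl_uv, uvband, mask$mask) else NA_real_
  } else {
    b_uv <- NA_real_; s_uv <- NA_real_
  }

  structure(list(
    egg_id = egg_id, frame = mask$frame,
    spot_number = n_spots,
    mean_spot_size_mm2 = if (n_spots > 0) mean(mask$areas_px) * mm_per_px^2 else NA_real_,
    spottiness_pct = 100 * sum(mask$mask) / sum(roi_mask),
    B_VIS = mean(b_band), S_VIS = if (n_spots > 0) mean(s_band) else NA_real_,
    B_UV = b_uv, S_UV = s_uv,
    B_VIS_bands = b_band, S_VIS_bands = s_band,
    roi_area_px = sum(roi_mask), spot_area_px = sum(mask$mask),
    mm_per_px = mm_per_px), class = "spot_report")
}

#' @export
print.spot_report <- function(x, ...) {
  cat(sprintf("<spot_report> %s: %d spots, spottiness %.1f%%, B_VIS %.1f, S_VIS %.1f, B_UV %.1f, S_UV %.1f\n",
              x$egg_id, x$spot_number, x$spottiness_pct, x$B_VIS, x$S_VIS, x$B_UV, x$S_UV))
  invisible(x)
}

#' Ordered seven-trait vector of a spot report
#'
#' Fixed ordering matching the PCA variable order: spot number, mean spot
#' size, spottiness, background VIS, spot VIS, background UV, spot UV.
#'
#' @param report a `spot_report`.
#' @return named numeric vector of length 7 (NA in the S slots for a
#'   spotless egg).
#' @export
trait_vector <- function(report) {
  stopifnot(inherits(report, "spot_report"))
  if (report$spot_number > 0 &&
      (is.na(report$mean_spot_size_mm2) || is.na(report$S_VIS))) {
    stop("inconsistent report: spots present but spot statistics missing")
  }
  c(spot_number = report$spot_number,
    spot_size = report$mean_spot_size_mm2,
    spottiness = report$spottiness_pct,
    B_VIS = report$B_VIS, S_VIS = report$S_VIS,
    B_UV = report$B_UV, S_UV = report$S_UV)
}
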