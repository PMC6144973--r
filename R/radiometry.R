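#' Raw camera images
#'
#' A `raw_image` holds integer-like camera counts for one or more bands
#' together with its bit depth. Bands are stored as a named list of numeric
#' matrices (rows = image rows, columns = image columns).
#'
#' @param bands named list of numeric matrices, one per band (e.g. R, G, B or
#'   UV). All matrices must share a dimension; counts must be non-negative.
#' @param bit_depth integer, bits per sample (8 or 16 for the supported
#'   formats).
#' @param linear logical, whether the counts are already proportional to
#'   radiance.
#' @return an object of class `raw_image`.
#' @export
raw_image <- function(bands, bit_depth = 16L, linear = FALSE) {
  stopifnot(is.list(bands), length(bands) > 0)
  nm <- names(bands)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))) {
    stop("bands must be uniquely named")
  }
  d <- dim(bands[[1]])
  for (b in bands) {
    if (!is.matrix(b) || !identical(dim(b), d)) stop("all bands must be matrices of equal dimension")
    if (any(b < 0)) stop("camera counts must be non-negative")
  }
  structure(list(bands = bands, bit_depth = as.integer(bit_depth), linear = isTRUE(linear)),
            class = "raw_image")
}

#' @export
dim.raw_image <- function(x) dim(x$bands[[1]])

#' @export
print.raw_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raw_image> %d x %d px, bands: %s, %d-bit, %s\n", d[1], d[2],
              paste(names(x$bands), collapse = ","), x$bit_depth,
              if (x$linear) "linearized" else "nonlinear"))
  invisible(x)
}

max_count <- function(img) 2^img$bit_depth - 1

#' Linearize a raw image with respect to radiance
#'
#' Inverts the camera response so that output counts are proportional to
#' scene radiance. The response is declared either as a gamma exponent
#' (counts = radiance^(1/gamma), so linearization raises normalized counts to
#' the power gamma) or as a lookup curve mapping normalized counts in [0, 1]
#' to normalized radiance; the curve must be strictly increasing and is
#' interpolated linearly.
#'
#' @param raw a [raw_image()].
#' @param response either a single number (the gamma exponent, > 0) or a list
#'   with elements `counts` and `radiance` giving a strictly increasing lookup
#'   curve on the normalized [0, 1] scale.
#' @return a linear [raw_image()] on the same count scale.
#' @export
linearize <- function(raw, response = 1) {
  stopifnot(inherits(raw, "raw_image"))
  mc <- max_count(raw)
  if (is.numeric(response) && length(response) == 1L) {
    if (response <= 0) stop("gamma exponent must be positive")
    f <- function(v) (v / mc)^response * mc
  } else if (is.list(response) && all(c("counts", "radiance") %in% names(response))) {
    cs <- response$counts; rs <- response$radiance
    if (length(cs) != length(rs) || length(cs) < 2L) stop("lookup curve needs matched vectors of length >= 2")
    o <- order(cs); cs <- cs[o]; rs <- rs[o]
    if (any(diff(rs) <= 0) || any(diff(cs) <= 0)) stop("invalid response: lookup curve must be strictly increasing")
    f <- function(v) {
      out <- stats::approx(cs, rs, xout = pmin(pmax(v / mc, min(cs)), max(cs)), rule = 2)$y * mc
      matrix(out, nrow = nrow(v))
    }
  } else {
    stop("response must be a gamma exponent or a counts/radiance lookup curve")
  }
  out <- lapply(raw$bands, function(b) {
    if (any(b > mc)) stop("counts exceed the declared bit depth")
    f(b)
  })
  raw_image(out, bit_depth = raw$bit_depth, linear = TRUE)
}

#' Percent-reflectance images
#'
#' The common currency of the image stage: per-band pixel maps in percent
#' reflectance, normalized so that the grey-standard patch means the
#' standard's nominal reflectance. Pixels that were saturated in the raw
#' image, and reflectances above 100 (specular highlights), are flagged in
#' `flagged` rather than clipped; downstream means use unflagged pixels.
#'
#' @param bands named list of numeric matrices (percent reflectance).
#' @param standard_counts named numeric vector: the per-band mean linear count
#'   of the standard patch used for normalization (provenance).
#' @param standard_value nominal percent reflectance of the standard.
#' @param flagged logical matrix of unreliable pixels (saturated or > 100%).
#' @return an object of class `reflectance_image`.
#' @export
reflectance_image <- function(bands, standard_counts, standard_value, flagged = NULL) {
  d <- dim(bands[[1]])
  if (is.null(flagged)) flagged <- matrix(FALSE, d[1], d[2])
  structure(list(bands = bands, standard_counts = standard_counts,
                 standard_value = standard_value, flagged = flagged),
            class = "reflectance_image")
}

#' @export
dim.reflectance_image <- function(x) dim(x$bands[[1]])

#' @export
print.reflectance_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<reflectance_image> %d x %d px, bands: %s, standard = %.1f%%, %d flagged px\n",
              d[1], d[2], paste(names(x$bands), collapse = ","), x$standard_value,
              sum(x$flagged)))
  invisible(x)
}

#' Normalize a linear image to percent reflectance against the grey standard
#'
#' Each band is scaled independently so that the mean linear count over the
#' standard patch maps to the standard's nominal reflectance (40% for the
#' Spectralon grey standard used throughout). Pixels within 1% of full scale
#' in the input are treated as saturated: they are excluded from the standard
#' mean and flagged in the output.
#'
#' @param linear a linearized [raw_image()].
#' @param standard_roi polygon (0-based px) delimiting the standard patch.
#' @param standard_value nominal reflectance of the standard in percent.
#' @return a [reflectance_image()].
#' @export
to_reflectance <- function(linear, standard_roi, standard_value = 40) {
  stopifnot(inherits(linear, "raw_image"))
  if (!isTRUE(linear$linear)) stop("image must be linearized before normalization")
  if (standard_value <= 0 || standard_value > 100) stop("standard_value must be in (0, 100]")
  d <- dim(linear)
  standard_roi <- as_polygon(standard_roi)
  if (any(standard_roi[, 1] < 0) || any(standard_roi[, 2] < 0) ||
      any(standard_roi[, 1] > d[2] - 1) || any(standard_roi[, 2] > d[1] - 1)) {
    stop("standard patch polygon lies outside the image")
  }
  patch <- polygon_mask(standard_roi, d)
  if (!any(patch)) stop("standard patch polygon is degenerate (covers no pixel)")
  mc <- max_count(linear)
  sat_thresh <- 0.99 * mc
  flagged <- matrix(FALSE, d[1], d[2])
  means <- numeric(0)
  out <- list()
  for (nm in names(linear$bands)) {
    b <- linear$bands[[nm]]
    sat <- b >= sat_thresh
    flagged <- flagged | sat
    usable <- patch & !sat
    if (!any(usable)) stop(sprintf("calibration failure: standard patch saturated in band %s", nm))
    m <- mean(b[usable])
    if (m <= 0) stop(sprintf("calibration failure: zero standard patch in band %s", nm))
    out[[nm]] <- b / m * standard_value
    means[nm] <- m
  }
  for (nm in names(out)) flagged <- flagged | (out[[nm]] > 100)
  reflectance_image(out, standard_counts = means, standard_value = standard_value,
                    flagged = flagged)
}

# Mean reflectance of one band over a logical mask, unflagged pixels only.
band_mean <- function(refl, band, mask) {
  use <- mask & !refl$flagged
  if (!any(use)) return(NA_real_)
  mean(refl$bands[[band]][use])
}
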