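#' Synthetic eggs and synthetic trait datasets
#'
#' Generators with full ground truth: ovoid egg image pairs (VIS 3-band + UV
#' 1-band raw camera images with a grey standard, scale bar, spots, camera
#' nonlinearity, noise, and a smooth space-variant VIS-to-UV warp) and
#' latitudinal trait datasets with site random intercepts. Every downstream
#' stage of the pipeline can be verified against these truths.
#'
#' @name eggsim
NULL

#' Ovoid radius function
#'
#' Two-parameter ovoid with an asymmetry term: at normalized axial position
#' u in [-1, 1], r(u) = (breadth/2) * sqrt(1 - u^2) * (1 + asym * u). asym = 0
#' gives a prolate spheroid; positive asym fattens the blunt end.
#'
#' @param u normalized axial position in [-1, 1].
#' @param length_mm,breadth_mm egg length and maximum breadth (mm).
#' @param asym asymmetry coefficient, |asym| < 1.
#' @return radius in mm.
#' @export
ovoid_radius <- function(u, length_mm, breadth_mm, asym = 0) {
  (breadth_mm / 2) * sqrt(pmax(0, 1 - u^2)) * (1 + asym * u)
}

#' Analytic volume and surface of the ovoid shape
#'
#' Solid-of-revolution integrals of the ovoid profile evaluated by adaptive
#' quadrature to 1e-6 relative tolerance; serves as the generator's shape
#' truth.
#'
#' @param shape list with `length_mm`, `breadth_mm`, `asym`.
#' @return list with `volume_mm3`, `surface_mm2`, `sv_per_mm`.
#' @export
ovoid_metrics <- function(shape) {
  L <- shape$length_mm; B <- shape$breadth_mm; a <- shape$asym %||% 0
  if (L <= 0 || B <= 0 || abs(a) >= 1) stop("invalid ovoid shape parameters")
  c2 <- B / 2
  r <- function(u) ovoid_radius(u, L, B, a)
  # dr/dt with t = (u + 1) L / 2 => dr/dt = r'(u) * 2/L
  rp <- function(u) c2 * (-u / sqrt(pmax(1e-300, 1 - u^2)) * (1 + a * u) +
                          sqrt(pmax(0, 1 - u^2)) * a)
  v <- pi * (L / 2) * stats::integrate(function(u) r(u)^2, -1, 1,
                                       rel.tol = 1e-8)$value
  s <- 2 * pi * (L / 2) * stats::integrate(function(u) r(u) * sqrt(1 + (rp(u) * 2 / L)^2),
                                           -1, 1, rel.tol = 1e-8)$value
  list(volume_mm3 = v, surface_mm2 = s, sv_per_mm = s / v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a smooth space-variant VIS-to-UV warp
#'
#' Returns a displacement field d(p) such that a VIS point p corresponds to
#' the UV point p + d(p), plus a sampler of exact control-point pairs.
#' Styles: `identity` (zero displacement), `affine` (d(p) = A p + b - p for a
#' supplied affine map, pure translation by default), and `smooth_bumps`
#' (a sum of Gaussian bumps rescaled so the maximum displacement magnitude on
#' the pixel grid equals `magnitude_px`).
#'
#' @param style one of "identity", "affine", "smooth_bumps".
#' @param magnitude_px maximum displacement magnitude in px (ignored for
#'   identity/affine).
#' @param seed integer seed controlling bump placement and point sampling.
#' @param width,height extent of the pixel domain the warp covers.
#' @param affine optional list(A = 2x2 matrix, b = length-2 vector) for the
#'   affine style; default is the pure translation b = c(3, -2).
#' @return an object of class `egg_warp` with elements `displace(x, y)`
#'   (vectorized, returns a 2-column matrix), `sample_points(n, region)`,
#'   `field(dim)` (dense displacement arrays), and `invert(x, y)`.
#' @export
make_warp <- function(style = c("smooth_bumps", "identity", "affine"),
                      magnitude_px = 4, seed = 1L,
                      width = 320L, height = 240L, affine = NULL) {
  style <- match.arg(style)
  if (magnitude_px < 0) stop("magnitude_px must be >= 0")
  if (style == "identity") {
    displace <- function(x, y) cbind(dx = rep(0, length(x)), dy = rep(0, length(x)))
  } else if (style == "affine") {
    if (is.null(affine)) affine <- list(A = diag(2), b = c(3, -2))
    A <- affine$A; b <- affine$b
    displace <- function(x, y) {
      p <- cbind(x, y)
      q <- t(A %*% t(p)) + rep(b, each = length(x))
      cbind(dx = q[, 1] - x, dy = q[, 2] - y)
    }
  } else {
    # a handful of Gaussian bumps; amplitude rescaled on the grid below
    rs <- local({ set.seed(seed); list(cx = runif(4, 0, width), cy = runif(4, 0, height),
                                       sx = runif(4, width / 6, width / 3),
                                       ax = rnorm(4), ay = rnorm(4)) })
    raw_disp <- function(x, y) {
      dx <- numeric(length(x)); dy <- numeric(length(x))
      for (k in 1:4) {
        w <- exp(-((x - rs$cx[k])^2 + (y - rs$cy[k])^2) / (2 * rs$sx[k]^2))
        dx <- dx + rs$ax[k] * w
        dy <- dy + rs$ay[k] * w
      }
      cbind(dx = dx, dy = dy)
    }
    gx <- seq(0, width - 1, length.out = 81)
    gy <- seq(0, height - 1, length.out = 61)
    g <- expand.grid(x = gx, y = gy)
    d0 <- raw_disp(g$x, g$y)
    mmax <- max(sqrt(d0[, 1]^2 + d0[, 2]^2))
    sc <- if (mmax > 0) magnitude_px / mmax else 0
    displace <- function(x, y) raw_disp(x, y) * sc
  }

  invert <- function(x, y) {
    if (style == "identity") return(cbind(x = x, y = y))
    if (style == "affine") {
      A <- affine$A %||% diag(2); b <- affine$b %||% c(3, -2)
      p <- sweep(cbind(x, y), 2, b)
      q <- t(solve(A, t(p)))
      return(cbind(x = q[, 1], y = q[, 2]))
    }
    # fixed-point iteration p <- q - d(p); contraction for smooth small warps
    px <- x; py <- y
    for (i in 1:25) {
      d <- displace(px, py)
      px <- x - d[, 1]; py <- y - d[, 2]
    }
    cbind(x = px, y = py)
  }

  sample_points <- function(n, region = NULL) {
    if (n < 13) warning("fewer than 13 control points: downstream LWM fit will reject this set")
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pts) < n && tries < 200 * n) {
      m <- n - nrow(pts)
      cand <- cbind(runif(m, 0, width - 1), runif(m, 0, height - 1))
      keep <- if (is.null(region)) rep(TRUE, m) else point_in_polygon(cand[, 1], cand[, 2], region)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
      tries <- tries + m
    }
    if (nrow(pts) < n) stop("could not sample the requested number of control points in the region")
    pts <- pts[seq_len(n), , drop = FALSE]
    d <- displace(pts[, 1], pts[, 2])
    data.frame(x_vis = pts[, 1], y_vis = pts[, 2],
               x_uv = pts[, 1] + d[, 1], y_uv = pts[, 2] + d[, 2])
  }

  field <- function(dim) {
    xs <- rep(seq_len(dim[2]) - 1, each = dim[1])
    ys <- rep(seq_len(dim[1]) - 1, times = dim[2])
    d <- displace(xs, ys)
    list(dx = matrix(d[, 1], dim[1], dim[2]), dy = matrix(d[, 2], dim[1], dim[2]))
  }

  structure(list(style = style, magnitude_px = magnitude_px, seed = seed,
                 width = width, height = height,
                 displace = displace, invert = invert,
                 sample_points = sample_points, field = field),
            class = "egg_warp")
}

default_reflectance <- function() {
  list(background = c(R = 45, G = 42, B = 38, UV = 30),
       spot = c(R = 20, G = 18, B = 16, UV = 12),
       surround = c(R = 25, G = 25, B = 25, UV = 18),
       scale_bar = c(R = 5, G = 5, B = 5, UV = 4),
       standard = 40)
}

default_shape <- function() list(length_mm = 32.5, breadth_mm = 23.5, asym = 0.12)

#' Render a synthetic egg image pair with full ground truth
#'
#' Builds an analytic scene (ovoid egg with per-band background reflectance,
#' darker spots, a grey standard patch, and a scale bar) and photographs it
#' twice: a 3-band VIS image in the VIS frame and a 1-band UV image in the
#' warped UV frame. Camera counts follow counts = L^(1/gamma) scaled to the
#' bit depth, where L is linear radiance, with additive Gaussian read noise;
#' the UV exposure carries 3x the VIS noise to mimic its degraded
#' signal-to-noise ratio.
#'
#' @param shape_params list(length_mm, breadth_mm, asym).
#' @param reflectance_params list with `background`, `spot` (named per-band
#'   percent reflectances with elements R, G, B, UV), `surround`, `scale_bar`,
#'   and `standard` (scalar percent, default 40).
#' @param n_spots number of circular spots to place inside the RoI.
#' @param warp_params list passed to [make_warp()] (style, magnitude_px).
#' @param gamma camera response exponent (1 = linear sensor).
#' @param noise_sd additive noise SD in count units (16-bit scale) for the
#'   VIS exposure.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param mm_per_px image scale; width/height image size in px.
#' @param width,height image size (px).
#' @param spot_radius_px range of spot radii (px).
#' @param n_control_points number of VIS-UV control-point pairs sampled
#'   inside the RoI.
#' @param roi_scale scale of the RoI polygon relative to the egg outline
#'   (1 = the outline itself; < 1 insets it as a hand-drawn RoI would).
#' @param min_separation_px minimum gap between spot boundaries, keeping the
#'   placed spot count equal to the connected-component count.
#' @return an object of class `egg_image_truth`; see Details.
#' @details The returned list contains `vis_raw` and `uv_raw`
#'   ([raw_image()]s), `spot_mask_vis`, `roi`, `standard_patch` (`polygon` in
#'   the VIS frame, `polygon_uv` marking the same patch in the warped UV
#'   frame, and `value`), `scale_bar` (two points + `known_mm`), `warp` (the `egg_warp`),
#'   `warp_truth` (dense VIS-to-UV displacement field), `control_points`,
#'   `band_reflectance_truth`, `shape_truth` (parameters plus analytic
#'   volume/surface), `spottiness_truth_pct`, `gamma`, `noise_sd`,
#'   `mm_per_px`.
#' @export
make_egg_image <- function(shape_params = default_shape(),
                           reflectance_params = default_reflectance(),
                           n_spots = 15,
                           warp_params = list(style = "smooth_bumps", magnitude_px = 4),
                           gamma = 2.2, noise_sd = 40, seed = 1L,
                           mm_per_px = 0.15, width = 320L, height = 240L,
                           spot_radius_px = c(3, 8),
                           n_control_points = 20L,
                           roi_scale = 1, min_separation_px = 3) {
  rp <- reflectance_params
  for (part in c("background", "spot")) {
    if (any(rp[[part]] <= 0) || any(rp[[part]] > 100)) stop("reflectances must be in (0, 100]")
  }
  if (any(rp$spot >= rp$background)) stop("spots must be darker than the background in every band")
  if (n_spots < 0) stop("n_spots must be >= 0")
  set.seed(seed)

  L_px <- shape_params$length_mm / mm_per_px
  B_px <- shape_params$breadth_mm / mm_per_px
  cx <- 0.56 * width; cy <- 0.48 * height
  if (L_px > 0.9 * width || B_px > 0.75 * height) stop("egg does not fit in the image")

  # RoI: the egg outline itself, 72 vertices (x = half-length * cos phi,
  # y = half-breadth * sin phi * (1 + asym cos phi) parametrizes the ovoid)
  asym <- shape_params$asym %||% 0
  phi <- seq(0, 2 * pi, length.out = 73)[-73]
  roi <- cbind(x = cx + roi_scale * (L_px / 2) * cos(phi),
               y = cy + roi_scale * (B_px / 2) * sin(phi) * (1 + asym * cos(phi)))

  standard_patch <- cbind(x = c(10, 60, 60, 10), y = c(10, 10, 55, 55))
  scale_known_mm <- 15
  scale_points <- rbind(c(20, 220), c(20 + scale_known_mm / mm_per_px, 220))

  # spot placement: centers + radii such that each disk lies inside the RoI
  radii <- numeric(0); centers <- matrix(NA_real_, 0, 2)
  if (n_spots > 0) {
    tries <- 0
    while (length(radii) < n_spots) {
      tries <- tries + 1
      if (tries > 300 * n_spots) stop("placement failure: could not place all spots inside the RoI")
      r <- runif(1, spot_radius_px[1], spot_radius_px[2])
      u <- runif(1, -0.92, 0.92)
      x <- cx + u * (L_px / 2) * 0.92
      ymax <- 0.92 * ovoid_radius(u, shape_params$length_mm, shape_params$breadth_mm,
                                  shape_params$asym %||% 0) / mm_per_px
      y <- cy + runif(1, -ymax, ymax)
      ring <- cbind(x + r * cos(phi), y + r * sin(phi))
      if (!all(point_in_polygon(ring[, 1], ring[, 2], roi))) next
      if (length(radii) > 0) {
        dd <- sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2)
        if (any(dd < radii + r + min_separation_px)) next
      }
      centers <- rbind(centers, c(x, y)); radii <- c(radii, r)
    }
  }

  # analytic scene: per-band reflectance at continuous VIS coordinates
  scene <- function(x, y, band) {
    refl <- rep(rp$surround[[band]], length(x))
    onstd <- x >= 10 & x <= 60 & y >= 10 & y <= 55
    refl[onstd] <- rp$standard
    onbar <- x >= scale_points[1, 1] & x <= scale_points[2, 1] & y >= 215 & y <= 225
    refl[onbar] <- rp$scale_bar[[band]]
    u <- (x - cx) / (L_px / 2)
    redge <- ovoid_radius(pmax(-1, pmin(1, u)), shape_params$length_mm,
                          shape_params$breadth_mm, shape_params$asym %||% 0) / mm_per_px
    onegg <- abs(u) <= 1 & abs(y - cy) <= redge
    refl[onegg] <- rp$background[[band]]
    if (length(radii) > 0) {
      for (k in seq_along(radii)) {
        onspot <- (x - centers[k, 1])^2 + (y - centers[k, 2])^2 <= radii[k]^2
        refl[onegg & onspot] <- rp$spot[[band]]
      }
    }
    refl
  }

  warp <- do.call(make_warp, c(warp_params, list(seed = seed + 1L, width = width, height = height)))

  bit_depth <- 16L
  mc <- 2^bit_depth - 1
  illum <- 0.8  # linear radiance of a 100% reflector; keeps the scene off full scale
  render <- function(x, y, band, sd_counts) {
    L <- scene(x, y, band) / 100 * illum
    counts <- L^(1 / gamma) * mc
    if (sd_counts > 0) counts <- counts + rnorm(length(counts), 0, sd_counts)
    counts <- round(pmin(pmax(counts, 0), mc))
    matrix(counts, nrow = height, ncol = width)
  }
  xs <- rep(seq_len(width) - 1, each = height)
  ys <- rep(seq_len(height) - 1, times = width)

  vis_raw <- raw_image(list(R = render(xs, ys, "R", noise_sd),
                            G = render(xs, ys, "G", noise_sd),
                            B = render(xs, ys, "B", noise_sd)),
                       bit_depth = bit_depth)

  # UV frame: pixel q shows the scene at the VIS point mapping to q
  src <- warp$invert(xs, ys)
  uv_counts <- {
    L <- scene(src[, 1], src[, 2], "UV") / 100 * illum
    counts <- L^(1 / gamma) * mc
    uv_sd <- 3 * noise_sd
    if (uv_sd > 0) counts <- counts + rnorm(length(counts), 0, uv_sd)
    matrix(round(pmin(pmax(counts, 0), mc)), nrow = height, ncol = width)
  }
  uv_raw <- raw_image(list(UV = uv_counts), bit_depth = bit_depth)

  # truth rasters in the VIS frame
  roi_mask <- polygon_mask(roi, c(height, width))
  spot_mask <- matrix(FALSE, height, width)
  if (length(radii) > 0) {
    for (k in seq_along(radii)) {
      spot_mask <- spot_mask |
        matrix((xs - centers[k, 1])^2 + (ys - centers[k, 2])^2 <= radii[k]^2,
               height, width)
    }
    spot_mask <- spot_mask & roi_mask
  }

  control_points <- warp$sample_points(n_control_points, region = roi)
  shape_truth <- c(shape_params, ovoid_metrics(shape_params))

  # the standard patch as seen in the UV frame: forward-map the corners and
  # inset towards the centroid to stay clear of the (slightly curved) edges
  dstd <- warp$displace(standard_patch[, 1], standard_patch[, 2])
  std_uv <- standard_patch + dstd
  ctr <- colMeans(std_uv)
  std_uv <- sweep(sweep(std_uv, 2, ctr) * 0.85, 2, ctr, `+`)

  structure(list(
    vis_raw = vis_raw, uv_raw = uv_raw,
    spot_mask_vis = spot_mask, roi = roi,
    standard_patch = list(polygon = standard_patch, polygon_uv = std_uv,
                          value = rp$standard),
    scale_bar = list(points = scale_points, known_mm = scale_known_mm),
    warp = warp, warp_truth = warp$field(c(height, width)),
    control_points = control_points,
    band_reflectance_truth = list(background = rp$background, spot = rp$spot),
    shape_truth = shape_truth,
    spot_centers = centers, spot_radii = radii,
    spottiness_truth_pct = 100 * sum(spot_mask) / sum(roi_mask),
    n_spots = n_spots, gamma = gamma, noise_sd = noise_sd,
    mm_per_px = mm_per_px, seed = seed), class = "egg_image_truth")
}

#' Default coefficients of the synthetic trait dataset
#'
#' Fixed-effect structure for the first trait axis (PC1): a linear year
#' effect (0.027 per year, centered at 1915), a linear surface-to-volume
#' effect (69.850 per mm^-1, centered at the dataset mean), and a quartic
#' response to breeding-season insolation with turning points near 0.57,
#' 0.67 and 0.82 kW/m^2; PC2 carries no fixed structure (site intercept +
#' noise only). Variance components are set so that the expected marginal
#' and conditional R^2 of the PC1 generating model are about 0.45 and 0.48.
#'
#' @return named list of generator coefficients.
#' @export
trait_coeffs <- function() {
  list(beta_year = 0.027, year_ref = 1915,
       beta_sv = 69.850,
       quartic_k = 13269.2, quartic_ref = 0.685,
       pc2_sigma_alpha = 0.645, pc2_sigma_eps = 1.060)
}

# antiderivative of (u - .57)(u - .67)(u - .82)
.quartic_H <- function(u) u^4 / 4 - (2.06 / 3) * u^3 + (1.3987 / 2) * u^2 - 0.313158 * u

#' Quartic insolation response of the synthetic PC1
#'
#' @param ins insolation in kW/m^2.
#' @param coeffs coefficient list from [trait_coeffs()].
#' @return effect on the PC1 scale (0 at the reference insolation).
#' @export
insolation_effect <- function(ins, coeffs = trait_coeffs()) {
  -coeffs$quartic_k * (.quartic_H(ins) - .quartic_H(coeffs$quartic_ref))
}

#' Generate a synthetic latitudinal trait dataset
#'
#' Emulates the study design: collection sites spread over 11.35-54.52
#' degrees N with a decreasing insolation gradient, eggs collected 1858-1972,
#' site random intercepts, and the fixed-effect structure of
#' [trait_coeffs()]. Each site receives a Poisson number of eggs; sites
#' drawing zero eggs are dropped.
#'
#' @param n_sites number of collection sites.
#' @param eggs_per_site_mean Poisson mean clutch count per site (defaults to
#'   110/30, giving an expected study size of 110 eggs).
#' @param coeffs generator coefficients; see [trait_coeffs()].
#' @param sigma_alpha SD of the PC1 site random intercept.
#' @param sigma_eps residual SD of PC1.
#' @param seed integer seed.
#' @return an object of class `trait_table_truth`: list with `table` (the
#'   per-egg data.frame: egg, site, latitude, longitude, year, insolation,
#'   temperature, sv, PC1, PC2) and `params` (all generator parameters and
#'   the drawn site intercepts).
#' @export
make_trait_dataset <- function(n_sites = 30, eggs_per_site_mean = 110 / 30,
                               coeffs = trait_coeffs(),
                               sigma_alpha = 0.363, sigma_eps = 1.513,
                               seed = 1L) {
  if (n_sites < 2) stop("n_sites must be >= 2")
  if (eggs_per_site_mean <= 0) stop("invalid configuration: eggs_per_site_mean must be positive")
  if (sigma_alpha <= 0 || sigma_eps <= 0) stop("sigma_alpha and sigma_eps must be positive")
  set.seed(seed)

  lat <- runif(n_sites, 11.35, 54.52)
  lon <- runif(n_sites, -13.86, 77.25)
  ins <- 0.92 - 0.00973 * (lat - 11.35) + rnorm(n_sites, 0, 0.015)
  temp <- 37 - 0.45 * (lat - 11.35) + rnorm(n_sites, 0, 1.5)
  alpha1 <- rnorm(n_sites, 0, sigma_alpha)
  alpha2 <- rnorm(n_sites, 0, coeffs$pc2_sigma_alpha)
  n_eggs <- stats::rpois(n_sites, eggs_per_site_mean)

  site <- rep(seq_len(n_sites), n_eggs)
  n <- length(site)
  if (n == 0) stop("no eggs drawn; increase eggs_per_site_mean")
  year <- sample(1858:1972, n, replace = TRUE)
  sv <- rnorm(n, 0.236, 0.008)
  sv_ref <- mean(sv)

  fixed1 <- coeffs$beta_year * (year - coeffs$year_ref) +
    insolation_effect(ins[site], coeffs) +
    coeffs$beta_sv * (sv - sv_ref)
  pc1 <- fixed1 + alpha1[site] + rnorm(n, 0, sigma_eps)
  pc2 <- alpha2[site] + rnorm(n, 0, coeffs$pc2_sigma_eps)

  tab <- data.frame(egg = sprintf("egg%03d", seq_len(n)),
                    site = sprintf("site%02d", site),
                    latitude = lat[site], longitude = lon[site],
                    year = year, insolation = ins[site], temperature = temp[site],
                    sv = sv, PC1 = pc1, PC2 = pc2,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 params = list(n_sites = n_sites,
                               eggs_per_site_mean = eggs_per_site_mean,
                               coeffs = coeffs, sigma_alpha = sigma_alpha,
                               sigma_eps = sigma_eps, sv_ref = sv_ref,
                               site_intercepts_pc1 = alpha1,
                               site_intercepts_pc2 = alpha2, seed = seed)),
            class = "trait_table_truth")
}
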