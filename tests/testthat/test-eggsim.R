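test_that("warp styles honour their contracts", {
  w0 <- make_warp("identity", seed = 1)
  g <- expand.grid(x = seq(0, 319, by = 20), y = seq(0, 239, by = 20))
  expect_true(all(w0$displace(g$x, g$y) == 0))

  wt <- make_warp("affine", seed = 1, affine = list(A = diag(2), b = c(5, -3)))
  pairs <- wt$sample_points(15)
  expect_equal(pairs$x_uv - pairs$x_vis, rep(5, 15))
  expect_equal(pairs$y_uv - pairs$y_vis, rep(-3, 15))

  wb <- make_warp("smooth_bumps", magnitude_px = 4, seed = 2)
  d <- wb$displace(g$x, g$y)
  expect_true(max(sqrt(d[, 1]^2 + d[, 2]^2)) <= 4 + 1e-9)

  expect_warning(wb$sample_points(10), "13")
})

test_that("egg images are deterministic and carry consistent ground truth", {
  a <- make_egg_image(seed = 3, n_spots = 6)
  b <- make_egg_image(seed = 3, n_spots = 6)
  expect_identical(a$vis_raw$bands, b$vis_raw$bands)
  expect_identical(a$uv_raw$bands, b$uv_raw$bands)
  expect_identical(a$control_points, b$control_points)

  # control points inside the RoI and exactly consistent with the warp field
  cp <- a$control_points
  expect_true(all(ovoscope:::point_in_polygon(cp$x_vis, cp$y_vis, a$roi)))
  d <- a$warp$displace(cp$x_vis, cp$y_vis)
  expect_equal(cp$x_uv, cp$x_vis + d[, 1], tolerance = 1e-12)
  expect_equal(cp$y_uv, cp$y_vis + d[, 2], tolerance = 1e-12)

  # spots darker than background in every band, disjoint from standard/scale bar
  expect_true(all(a$band_reflectance_truth$spot < a$band_reflectance_truth$background))
  std_mask <- ovoscope:::polygon_mask(a$standard_patch$polygon, dim(a$spot_mask_vis))
  expect_false(any(a$spot_mask_vis & std_mask))

  z <- make_egg_image(seed = 4, n_spots = 0)
  expect_false(any(z$spot_mask_vis))
  expect_equal(z$spottiness_truth_pct, 0)
})

test_that("gamma-1 noiseless rendering equates background and standard counts", {
  rp <- default_reflectance <- list(background = c(R = 40, G = 40, B = 40, UV = 40),
                                    spot = c(R = 10, G = 10, B = 10, UV = 10),
                                    surround = c(R = 25, G = 25, B = 25, UV = 18),
                                    scale_bar = c(R = 5, G = 5, B = 5, UV = 4),
                                    standard = 40)
  egg <- make_egg_image(reflectance_params = rp, gamma = 1, noise_sd = 0,
                        n_spots = 0, seed = 9)
  std_mask <- ovoscope:::polygon_mask(egg$standard_patch$polygon, dim(egg$spot_mask_vis))
  roi_mask <- ovoscope:::polygon_mask(egg$roi, dim(egg$spot_mask_vis))
  r <- egg$vis_raw$bands$R
  expect_equal(unique(r[std_mask]), unique(r[roi_mask]))
})

test_that("radiometry round trip recovers the band reflectance truth", {
  egg <- make_egg_image(gamma = 2.2, noise_sd = 0, seed = 5)
  refl <- to_reflectance(linearize(egg$vis_raw, egg$gamma),
                         egg$standard_patch$polygon, egg$standard_patch$value)
  m <- mask_from_truth(egg$spot_mask_vis, egg$roi)
  bg <- m$roi_mask & !m$mask
  for (b in c("R", "G", "B")) {
    expect_lt(abs(mean(refl$bands[[b]][bg]) - egg$band_reflectance_truth$background[[b]]), 0.1)
    expect_lt(abs(mean(refl$bands[[b]][m$mask]) - egg$band_reflectance_truth$spot[[b]]), 0.1)
  }
})

test_that("ovoid metrics agree with closed forms and the trait generator is structured", {
  # prolate spheroid: a = 25, b = 15 (asym 0)
  sph <- ovoid_metrics(list(length_mm = 50, breadth_mm = 30, asym = 0))
  a <- 25; b <- 15
  expect_equal(sph$volume_mm3, 4 / 3 * pi * a * b^2, tolerance = 1e-6)
  e <- sqrt(1 - b^2 / a^2)
  s_true <- 2 * pi * b^2 * (1 + a / (b * e) * asin(e))
  expect_equal(sph$surface_mm2, s_true, tolerance = 1e-6)

  # degenerate noise/effects: PC1 an exact linear function of year
  cf <- trait_coeffs(); cf$quartic_k <- 0; cf$beta_sv <- 0
  d <- make_trait_dataset(coeffs = cf, sigma_alpha = 1e-9, sigma_eps = 1e-9, seed = 2)
  fit <- lm(PC1 ~ year, data = d$table)
  expect_lt(max(abs(resid(fit))), 1e-6)
  expect_equal(unname(coef(fit)[2]), 0.027, tolerance = 1e-6)

  # expected study size ~ 110 eggs at defaults
  sizes <- vapply(1:40, function(s) nrow(make_trait_dataset(seed = s)$table), 0)
  expect_lt(abs(mean(sizes) - 110), 5)

  # one site id -> one covariate triple; sites share their intercept draw
  tab <- make_trait_dataset(seed = 6)$table
  per_site <- unique(tab[, c("site", "latitude", "insolation", "temperature")])
  expect_equal(nrow(per_site), length(unique(tab$site)))
  # insolation decreases with latitude in expectation
  expect_lt(cor(per_site$latitude, per_site$insolation), -0.9)

  expect_error(make_trait_dataset(eggs_per_site_mean = 0), "invalid configuration")
})
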