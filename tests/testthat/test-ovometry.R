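circle_poly <- function(cx, cy, r, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipse_poly <- function(cx, cy, a, b, n = 360, rot = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(x = cx + x * cos(rot) - y * sin(rot),
        y = cy + x * sin(rot) + y * cos(rot))
}

test_that("scale calibration is plain symmetric arithmetic", {
  p <- rbind(c(0, 0), c(100, 0))
  expect_equal(calibrate_scale(p, 10), 0.1)
  expect_equal(calibrate_scale(p[2:1, ], 10), 0.1)
  expect_error(calibrate_scale(rbind(c(1, 1), c(1, 1)), 10), "coincide")
})

test_that("profiles match closed forms for circles and ellipses", {
  prof <- extract_profile(circle_poly(100, 100, 50), mm_per_px = 0.2)
  inner <- prof$r[prof$t > 2 & prof$t < max(prof$t) - 2]
  expect_lt(max(abs(inner - sqrt(100 - (prof$t[prof$t > 2 & prof$t < max(prof$t) - 2] - 10)^2)) / 10), 0.005)

  prof2 <- extract_profile(ellipse_poly(150, 100, 100, 60), mm_per_px = 0.25)
  a <- 25; b <- 15
  t_mid <- prof2$t - a
  expected <- b * sqrt(pmax(0, 1 - (t_mid / a)^2))
  sel <- abs(t_mid) < 0.95 * a
  expect_lt(max(abs(prof2$r[sel] - expected[sel]) / b), 0.005)

  expect_error(extract_profile(cbind(c(0, 10, 10, 0), c(0, 10, 0, 10)), 0.1),
               "self-intersecting")
})

test_that("volume and surface match the sphere and spheroid closed forms", {
  prof <- extract_profile(circle_poly(100, 100, 100, n = 720), mm_per_px = 0.1)
  m <- volume_surface(prof)
  expect_lt(abs(m$volume_mm3 - 4188.79) / 4188.79, 0.005)
  expect_lt(abs(m$surface_mm2 - 1256.64) / 1256.64, 0.005)

  prof2 <- extract_profile(ellipse_poly(150, 100, 125, 75, n = 720), mm_per_px = 0.2)
  m2 <- volume_surface(prof2)
  a <- 25; b <- 15
  v_true <- 4 / 3 * pi * a * b^2
  e <- sqrt(1 - b^2 / a^2)
  s_true <- 2 * pi * b^2 * (1 + a / (b * e) * asin(e))
  expect_lt(abs(m2$volume_mm3 - v_true) / v_true, 0.005)
  expect_lt(abs(m2$surface_mm2 - s_true) / s_true, 0.005)
  expect_equal(m2$sv_per_mm, m2$surface_mm2 / m2$volume_mm3)
  # isoperimetric bound
  expect_gte(m2$surface_mm2, (36 * pi * m2$volume_mm3^2)^(1 / 3))
})

test_that("station refinement has converged at the default resolution", {
  roi <- ellipse_poly(150, 100, 120, 70, n = 720)
  m200 <- volume_surface(extract_profile(roi, 0.2, n_stations = 200))
  m400 <- volume_surface(extract_profile(roi, 0.2, n_stations = 400))
  expect_lt(abs(m400$volume_mm3 - m200$volume_mm3) / m200$volume_mm3, 0.001)
  expect_lt(abs(m400$surface_mm2 - m200$surface_mm2) / m200$surface_mm2, 0.001)
})

test_that("metrics obey the scaling law and rotation invariance", {
  roi <- ellipse_poly(150, 100, 100, 60, n = 720)
  m1 <- volume_surface(extract_profile(roi, 0.2))
  mk <- volume_surface(extract_profile(roi, 0.2 * 3))  # scale lengths by 3
  expect_equal(mk$volume_mm3, m1$volume_mm3 * 27, tolerance = 1e-6)
  expect_equal(mk$surface_mm2, m1$surface_mm2 * 9, tolerance = 1e-6)
  expect_equal(mk$sv_per_mm, m1$sv_per_mm / 3, tolerance = 1e-6)

  rot <- ellipse_poly(150, 100, 100, 60, n = 720, rot = 0.61)
  mr <- volume_surface(extract_profile(rot, 0.2))
  expect_lt(abs(mr$volume_mm3 - m1$volume_mm3) / m1$volume_mm3, 0.001)
  expect_lt(abs(mr$surface_mm2 - m1$surface_mm2) / m1$surface_mm2, 0.001)
})

test_that("the asymmetric ovoid fixture profile matches the generator truth", {
  egg <- make_egg_image(seed = 21, n_spots = 0)
  prof <- extract_profile(egg$roi, egg$mm_per_px)
  m <- volume_surface(prof)
  expect_lt(abs(m$volume_mm3 - egg$shape_truth$volume_mm3) / egg$shape_truth$volume_mm3, 0.01)
  expect_lt(abs(m$surface_mm2 - egg$shape_truth$surface_mm2) / egg$shape_truth$surface_mm2, 0.01)
  # radius function within 1% of the ovoid truth away from the poles
  L <- egg$shape_truth$length_mm
  u <- 2 * prof$t / max(prof$t) - 1
  r_true <- ovoid_radius(u, L, egg$shape_truth$breadth_mm, egg$shape_truth$asym)
  sel <- abs(u) < 0.9
  expect_lt(max(abs(prof$r[sel] - r_true[sel])) / max(r_true), 0.01)
})
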