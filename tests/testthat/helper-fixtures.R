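# Shared fixture builders; everything is generated in code at test time.

# flat multi-band reflectance image (percent values)
make_flat_refl <- function(nr, nc, values = c(R = 45, G = 42, B = 38)) {
  bands <- lapply(values, function(v) matrix(v, nr, nc))
  reflectance_image(bands, standard_counts = values, standard_value = 40)
}

disk_px <- function(nr, nc, cx, cy, r) {
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, times = nc)
  matrix((xs - cx)^2 + (ys - cy)^2 <= r^2, nr, nc)
}

# paint dark disks (reflectance drop in percentage points) into an image
paint_disks <- function(refl, centers, radii, drop_pp = 20) {
  nr <- nrow(refl$bands[[1]]); nc <- ncol(refl$bands[[1]])
  for (k in seq_len(nrow(centers))) {
    d <- disk_px(nr, nc, centers[k, 1], centers[k, 2], radii[k])
    for (b in names(refl$bands)) refl$bands[[b]][d] <- refl$bands[[b]][d] - drop_pp
  }
  refl
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# spot_mask object built from a truth raster (bypasses segmentation)
mask_from_truth <- function(spot_mask, roi, frame = "VIS") {
  roi_mask <- ovoscope:::polygon_mask(roi, dim(spot_mask))
  m <- spot_mask & roi_mask
  labels <- ovoscope:::label_components(m)
  areas <- if (max(labels) > 0) as.numeric(tabulate(labels[labels > 0])) else numeric(0)
  structure(list(mask = m, labels = labels, areas_px = areas,
                 roi_mask = roi_mask, roi = roi, frame = frame),
            class = "spot_mask")
}

# independent dense-covariance Gaussian log-likelihood oracle
bruteforce_loglik <- function(y, X, site, beta, sigma2_alpha, sigma2_eps,
                              criterion = "ML") {
  Z <- stats::model.matrix(~ factor(site) - 1)
  n <- length(y); p <- ncol(X)
  V <- sigma2_eps * diag(n) + sigma2_alpha * tcrossprod(Z)
  r <- y - X %*% beta
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  quad <- drop(t(r) %*% solve(V, r))
  if (criterion == "ML") {
    -0.5 * (n * log(2 * pi) + ld + quad)
  } else {
    A <- t(X) %*% solve(V, X)
    ldA <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * log(2 * pi) + ld + ldA + quad)
  }
}

# per-egg trait table with a single latent lightness factor (for PCA tests);
# spot_number is shifted by -1 so its log(x + 1) transform stays exactly
# log-linear in the factor
one_factor_traits <- function(n, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  data.frame(spot_number = exp(0.3 * -f + 2) - 1, spot_size = exp(-0.5 * f + 1),
             spottiness = exp(-0.4 * f + 1.5), B_VIS = exp(0.2 * f + 3.5),
             S_VIS = exp(0.25 * f + 2.8), B_UV = exp(0.3 * f + 3.2),
             S_UV = exp(0.35 * f + 2.4))
}

paper_pc1_loadings <- c(0.229, -0.360, -0.400, 0.428, 0.390, 0.406, 0.398)
paper_pc2_loadings <- c(-0.655, 0.523, 0.181, 0.218, 0.295, 0.220, 0.286)
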