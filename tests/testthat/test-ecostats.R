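test_that("log transform handles counts, zeros and ordering", {
  tab <- one_factor_traits(30, seed = 4)
  lt <- log_traits(tab)
  expect_equal(lt$spot_number, log(tab$spot_number + 1))
  expect_equal(lt$B_VIS, log(tab$B_VIS))
  # monotone order preserved for every trait
  for (v in ovoscope:::trait_names()) {
    expect_identical(order(tab[[v]]), order(lt[[v]]))
  }
  tab$spottiness[3] <- 0
  lt2 <- log_traits(tab)
  expect_true(lt2$exclude[3])
  tab$B_UV[1] <- -1
  expect_error(log_traits(tab), "domain error")
})

test_that("correlation PCA matches an independent eigen oracle", {
  set.seed(7)
  n <- 200
  tab <- as.data.frame(matrix(exp(rnorm(n * 7)), n, 7))
  names(tab) <- ovoscope:::trait_names()
  lt <- log_traits(tab)
  p <- pca_corr(lt)
  # oracle: prcomp on the scaled log traits
  o <- prcomp(scale(as.matrix(lt[, ovoscope:::trait_names()])))
  for (j in 1:7) {
    v <- o$rotation[, j]
    w <- p$loadings[, j]
    if (sum(v * w) < 0) v <- -v
    expect_lt(max(abs(v - w)), 1e-8)
  }
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  # sign conventions
  expect_gt(p$loadings["B_VIS", 1], 0)
  expect_gt(p$loadings["spot_size", 2], 0)
  # reconstruction from all components reproduces the standardized data
  Z <- scale(as.matrix(lt[, ovoscope:::trait_names()]))
  expect_lt(max(abs(Z %*% p$loadings %*% t(p$loadings) - Z)), 1e-8)
})

test_that("a single common factor loads entirely on PC1", {
  tab <- one_factor_traits(100, seed = 9)
  p <- pca_corr(log_traits(tab))
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-10)
  expect_error(pca_corr(log_traits(one_factor_traits(7))), "8 complete rows")
  tab$B_UV <- 5
  expect_error(pca_corr(log_traits(tab)), "constant")
})

test_that("the loading validator accepts sound vectors and rejects broken ones", {
  ok <- validate_loadings(cbind(paper_pc1_loadings, paper_pc2_loadings))
  expect_true(all(ok$norm_dev < 0.01))
  expect_lt(ok$max_dot, 0.01)
  expect_error(validate_loadings(cbind(2 * paper_pc1_loadings)), "unit norm")
  expect_error(validate_loadings(cbind(paper_pc1_loadings, paper_pc1_loadings)),
               "orthogonal")
})

test_that("AICc follows its defining formula and limits", {
  expect_equal(aicc(0, 0, 100), 0)
  expect_equal(aicc(-100, 5, 110), 210 + 60 / 104)
  expect_lt(abs(aicc(-100, 5, 1e6) - (200 + 10)), 1e-3)
  expect_error(aicc(-10, 10, 11), "undefined criterion")
})

test_that("Akaike weights reproduce the published spatio-temporal block", {
  w <- akaike_weights(c(2.24, 0, 4.81, 3.61, 16.12))
  expect_equal(round(w, 3), c(0.206, 0.632, 0.057, 0.104, 0.000))
  expect_equal(akaike_weights(0), 1)
  expect_equal(akaike_weights(c(3, 3)), c(0.5, 0.5))
  expect_equal(sum(akaike_weights(runif(10, 0, 20))), 1, tolerance = 1e-12)
  # invariance to a constant shift
  d <- c(0, 1.7, 4.2)
  expect_equal(akaike_weights(d), akaike_weights(d + 57.3))
})

test_that("the profiled fit matches the dense brute-force likelihood", {
  set.seed(11)
  for (rep in 1:5) {
    n_sites <- 8; nps <- 5
    site <- rep(seq_len(n_sites), each = nps)
    x <- rnorm(n_sites * nps)
    y <- 1 + 0.8 * x + rnorm(n_sites, 0, 1)[site] + rnorm(n_sites * nps)
    X <- cbind(1, x)
    for (crit in c("ML", "REML")) {
      f <- fit_lmm(y, X, site, crit)
      oracle <- bruteforce_loglik(y, X, site, f$beta, f$sigma2_alpha,
                                  f$sigma2_eps, crit)
      expect_equal(f$loglik, oracle, tolerance = 1e-6)
    }
  }
})

test_that("the fit collapses to ordinary least squares without site structure", {
  set.seed(12)
  n <- 120
  site <- rep(1:20, each = 6)
  x <- rnorm(n)
  # noise orthogonal to the site structure: the between-site variance
  # estimate is driven to the boundary with certainty
  e <- rnorm(n)
  e <- e - ave(e, site)
  y <- 2 - 0.5 * x + e
  X <- cbind(1, x)
  f <- fit_lmm(y, X, site, "ML")
  ols <- lm.fit(X, y)$coefficients
  expect_lt(max(abs(f$beta - ols)), 1e-6)
  expect_lt(f$sigma2_alpha, 1e-4)
  expect_true(any(f$boundary))
  expect_error(fit_lmm(y, X, rep(1, n), "ML"), "2 sites")
})

test_that("simulated-data estimates agree with lme4 and are unbiased", {
  skip_if_not_installed("lme4")
  set.seed(13)
  n_sites <- 30; nps <- 4
  site <- rep(seq_len(n_sites), each = nps)
  x <- rnorm(n_sites * nps)
  y <- 1 + 2 * x + rnorm(n_sites, 0, 1)[site] + rnorm(n_sites * nps, 0, 1)
  X <- cbind(1, x)
  f <- fit_lmm(y, X, site, "REML")
  l <- lme4::lmer(y ~ x + (1 | site), REML = TRUE)
  expect_equal(f$loglik, as.numeric(stats::logLik(l)), tolerance = 1e-6)
  expect_equal(unname(f$beta), unname(lme4::fixef(l)), tolerance = 1e-6)
  expect_equal(f$sigma2_alpha, as.numeric(lme4::VarCorr(l)$site), tolerance = 1e-5)

  # moderate replication check of unbiasedness
  est <- vapply(1:60, function(s) {
    set.seed(100 + s)
    yk <- 1 + 2 * x + rnorm(n_sites, 0, 1)[site] + rnorm(n_sites * nps, 0, 1)
    fit_lmm(yk, X, site, "ML")$beta[2]
  }, 0)
  expect_lt(abs(mean(est) - 2), 2 * sd(est) / sqrt(length(est)))
})

test_that("penalized smooths have sensible limiting behaviour", {
  set.seed(14)
  n <- 500
  site <- rep(1:25, each = 20)
  x <- runif(n)
  y_lin <- 1 + 2 * x + rnorm(25, 0, 0.5)[site] + rnorm(n)
  fs <- fit_smooth_term(y_lin, x, site, criterion = "REML")
  expect_lt(abs(fs$edf - 1), 0.2)

  # infinite penalty leaves exactly the least-squares line (theta_smooth = 0)
  z <- (x - mean(x)) / sd(x)
  X <- cbind(1, z)
  sb <- ovoscope:::smooth_basis(x, 5)
  prof <- ovoscope:::mixed_profile(c(0, 0), y_lin, X, list(site = matrix(0, n, 1) + 0,
                                                           smooth = sb$Z), "ML")
  ols <- lm.fit(X, y_lin)$coefficients
  expect_lt(max(abs(prof$beta - ols)), 1e-8)

  # quartic truth recovered by the capped spline
  truth <- function(v) 4 * (v - 0.2) * (v - 0.5) * (v - 0.8) * (v + 0.2) * 10
  y_q <- truth(x) + rnorm(25, 0, 0.5)[site] + rnorm(n, 0, 1)
  fq <- fit_smooth_term(y_q, x, site, criterion = "REML")
  grid_fit <- fq$fitted_smooth
  ctr <- function(v) v - mean(v)
  rmse <- sqrt(mean((ctr(grid_fit) - ctr(truth(x)))^2))
  expect_lt(rmse, 0.1 * diff(range(truth(x))))
  expect_gt(fq$edf, 2)
})

test_that("smooth-term complexity agrees with an independent GAMM fitter", {
  skip_if_not_installed("mgcv")
  set.seed(24)
  n <- 400
  site <- rep(1:20, each = 20)
  x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(20, 0, 0.5)[site] + rnorm(n, 0, 0.6)
  f <- fit_smooth_term(y, x, site, criterion = "REML")
  g <- mgcv::gam(y ~ s(x, k = 5, bs = "cr") + s(site, bs = "re"),
                 data = data.frame(y = y, x = x, site = factor(site)),
                 method = "REML")
  expect_lt(abs(f$edf - summary(g)$edf[1]), 0.5)
  # fitted smooth curves agree closely despite the different bases
  ctr <- function(v) v - mean(v)
  pf <- ctr(f$fitted_smooth)
  pg <- ctr(stats::predict(g, type = "terms")[, "s(x)"])
  expect_lt(sqrt(mean((pf - pg)^2)), 0.1 * diff(range(pg)))
})

test_that("the R-squared decomposition follows its definition", {
  fake <- list(fitted_fixed = c(rep(-2, 50), rep(2, 50)) * sqrt(2) / 2,
               sigma2_alpha = 1, sigma2_eps = 1)
  # population variance of fitted_fixed = 2
  r2 <- r2_nakagawa(fake)
  expect_equal(unname(r2), c(0.5, 0.75))
  fake$sigma2_alpha <- 0
  r20 <- r2_nakagawa(fake)
  expect_equal(r20[["R2m"]], r20[["R2c"]])
})

test_that("concurvity measures projection overlap between terms", {
  set.seed(15)
  n <- 1000
  site <- rep(1:20, each = 50)
  x1 <- rnorm(n)
  x2_ind <- rnorm(n)
  x2_cor <- 0.7 * x1 + sqrt(1 - 0.49) * rnorm(n)
  tab <- data.frame(site = site, a = x1, b = x2_ind, bc = x2_cor,
                    y = x1 + x2_ind + rnorm(n))
  f <- fit_model(tab, "y", list(term_linear("a"), term_linear("b")), "ML")
  expect_lt(concurvity(f, "a", "b"), 0.05)
  expect_equal(concurvity(f, "a", "a"), 1, tolerance = 1e-10)
  tab$y2 <- x1 + x2_cor + rnorm(n)
  f2 <- fit_model(tab, "y2", list(term_linear("a"), term_linear("bc")), "ML")
  expect_lt(abs(concurvity(f2, "a", "bc") - 0.49), 0.05)
  # for linear bases the measure reduces exactly to the squared correlation
  expect_equal(concurvity(f2, "a", "bc"), cor(x1, x2_cor)^2, tolerance = 1e-10)
})

test_that("model comparisons are coherent and reject mixed criteria", {
  d <- make_trait_dataset(seed = 31)
  f1 <- fit_model(d$table, "PC1", list(term_linear("year")), "ML")
  f2 <- fit_model(d$table, "PC1", list(), "ML")
  f3 <- fit_model(d$table, "PC1", list(term_linear("year")), "REML")
  cmp <- compare_models(list(f1, f2))
  expect_equal(sum(cmp$table$weight), 1, tolerance = 1e-6)
  expect_equal(min(cmp$table$dAICc), 0)
  expect_true(all(cmp$table$R2m <= cmp$table$R2c + 1e-12))
  expect_error(compare_models(list(f1, f3)), "invalid comparison")
  single <- compare_models(list(f1))
  expect_equal(single$table$weight, 1)
})

test_that("the selection workflow reproduces the study's table structure", {
  d <- make_trait_dataset(seed = 32)
  sel <- run_selection(d$table, "PC1")
  expect_equal(sel$spatio_temporal$table$label,
               c("Year + s(latitude)", "Year + latitude", "Latitude", "Year",
                 "Null model"))
  expect_equal(sel$spatio_temporal$table$df, c(6L, 5L, 4L, 4L, 3L))
  expect_equal(sel$environmental$table$df, c(9L, 8L, 8L, 7L, 7L, 8L, 9L, 3L))
  expect_equal(sum(sel$spatio_temporal$table$weight), 1, tolerance = 1e-6)
  expect_equal(sum(sel$environmental$table$weight), 1, tolerance = 1e-6)
  expect_true(is.finite(sel$random_effect$delta_aicc))
  # single-site degenerate table is refused
  tab1 <- d$table; tab1$site <- "siteA"
  expect_error(run_selection(tab1, "PC1"), "2 sites")
})
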