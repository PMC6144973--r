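test_that("configurations are validated strictly", {
  expect_error(read_config(list(seed = 1, bogus_key = 2)), "unknown configuration keys")
  expect_error(read_config(list(paths = list())), "seed")
  expect_error(read_config(list(seed = 1, radiometry = list(standard_value = 0))),
               "standard_value")
  cfg <- read_config(list(seed = 5))
  expect_equal(cfg$seed, 5L)
  expect_equal(cfg$radiometry$gamma, 2.2)
  # YAML round trip
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 9, n_images = 1), f)
  expect_equal(read_config(f)$seed, 9L)
})

test_that("simulation is deterministic and respects n_images = 0", {
  base <- tempfile()
  cfg <- default_config(); cfg$n_images <- 1
  m1 <- cmd_simulate(cfg, base_dir = base)
  expect_error(cmd_simulate(cfg, base_dir = base), "not empty")
  m2 <- cmd_simulate(cfg, base_dir = base, force = TRUE)
  expect_identical(m1, m2)
  expect_true("traits_truth.csv" %in% m1$file)

  base0 <- tempfile()
  cfg0 <- default_config(); cfg0$n_images <- 0; cfg0$simulate$traits <- FALSE
  m0 <- cmd_simulate(cfg0, base_dir = base0)
  expect_equal(nrow(m0), 0)
  unlink(c(base, base0), recursive = TRUE)
})

test_that("measurement over a noiseless fixture recovers the truth table", {
  base <- tempfile()
  cfg <- default_config()
  cfg$n_images <- 1
  cfg$simulate$noise_sd <- 0
  cmd_simulate(cfg, base_dir = base)
  rep1 <- cmd_measure(cfg, base_dir = base)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$flag, "")
  truth <- jsonlite::read_json(file.path(base, "images", "egg001_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(rep1$spot_number, truth$n_spots)
  expect_lt(abs(rep1$spottiness - truth$spottiness_truth_pct), 1)
  bg_truth <- unlist(truth$band_reflectance_truth$background)
  expect_lt(abs(rep1$B_VIS - mean(bg_truth[c("R", "G", "B")])), 0.5)
  expect_lt(abs(rep1$B_UV - bg_truth[["UV"]]), 1)
  expect_lt(abs(rep1$volume_mm3 - truth$shape_truth$volume_mm3) / truth$shape_truth$volume_mm3, 0.01)
  expect_equal(rep1$mm_per_px, truth$mm_per_px, tolerance = 1e-6)

  # CSV round-trips through the package reader without loss
  disk <- utils::read.csv(file.path(base, "outputs", "egg_report.csv"),
                          stringsAsFactors = FALSE)
  expect_equal(disk$spottiness, rep1$spottiness, tolerance = 1e-9)
  expect_equal(disk$volume_mm3, rep1$volume_mm3, tolerance = 1e-9)
  unlink(base, recursive = TRUE)
})

test_that("eggs with too few control points are flagged with blank UV fields", {
  base <- tempfile()
  cfg <- default_config(); cfg$n_images <- 1; cfg$simulate$noise_sd <- 0
  cmd_simulate(cfg, base_dir = base)
  fj <- file.path(base, "images", "egg001_truth.json")
  truth <- jsonlite::read_json(fj, simplifyVector = TRUE)
  truth$control_points <- truth$control_points[1:10, ]
  jsonlite::write_json(truth, fj, auto_unbox = TRUE, digits = NA)
  rep1 <- cmd_measure(cfg, base_dir = base)
  expect_equal(rep1$flag, "uv_unavailable")
  expect_true(is.na(rep1$B_UV) && is.na(rep1$S_UV))
  expect_false(is.na(rep1$B_VIS))
  unlink(base, recursive = TRUE)
})

test_that("an empty input directory yields an empty report with the schema", {
  base <- tempfile()
  dir.create(file.path(base, "images"), recursive = TRUE)
  rep0 <- cmd_measure(default_config(), base_dir = base)
  expect_equal(nrow(rep0), 0)
  expect_true(all(c("egg", "spottiness", "B_UV", "sv_per_mm", "flag") %in% names(rep0)))
  unlink(base, recursive = TRUE)
})

test_that("the analysis stage writes the study-shaped comparison tables", {
  base <- tempfile()
  dir.create(base)
  d <- make_trait_dataset(seed = 41)
  cfg <- default_config()
  sel <- cmd_analyze(cfg, base_dir = base, traits = d$table)
  st <- utils::read.csv(file.path(base, "outputs", "spatio_temporal_PC1.csv"))
  expect_equal(st$label, c("Year + s(latitude)", "Year + latitude", "Latitude",
                           "Year", "Null model"))
  for (f in dir(file.path(base, "outputs"), pattern = "^(spatio|environ).*csv$",
                full.names = TRUE)) {
    tab <- utils::read.csv(f)
    expect_equal(sum(tab$weight), 1, tolerance = 1e-6)
  }
  expect_true(file.exists(file.path(base, "outputs", "fit_audit.json")))
  expect_error(cmd_analyze(cfg, base_dir = base,
                           traits = d$table[, setdiff(names(d$table), "insolation")]),
               "missing column")
  # PCA stage engages when the seven trait columns are present
  set.seed(6)
  tt <- one_factor_traits(40, seed = 2)
  tt$site <- rep(sprintf("s%d", 1:8), each = 5)
  tt$latitude <- rep(seq(12, 54, length.out = 8), each = 5)
  tt$year <- sample(1858:1972, 40, replace = TRUE)
  tt$insolation <- 0.9 - 0.01 * (tt$latitude - 12) + rep(rnorm(8, 0, 0.02), each = 5)
  tt$temperature <- 35 - 0.4 * (tt$latitude - 12) + rep(rnorm(8, 0, 1.5), each = 5)
  tt$sv <- rnorm(40, 0.236, 0.008)
  cmd_analyze(cfg, base_dir = base, traits = tt)
  expect_true(file.exists(file.path(base, "outputs", "pca_loadings.csv")))
  unlink(base, recursive = TRUE)
})
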