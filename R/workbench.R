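#' Orchestration: simulate, measure, analyze
#'
#' The workbench ties the pipeline together behind three commands driven by
#' a YAML configuration with a mandatory seed: `cmd_simulate` writes a
#' fixture directory of synthetic egg image pairs with truth sidecars and a
#' synthetic trait table; `cmd_measure` runs radiometry, spot segmentation,
#' UV alignment and morphometry over every egg and writes the per-egg CSV
#' report; `cmd_analyze` runs the PCA and the model-selection workflow on a
#' trait table and writes the comparison tables and fit audits.
#'
#' @name workbench
NULL

config_keys <- function() {
  c("seed", "paths", "n_images", "radiometry", "segmentation", "lwm",
    "ovometry", "stats", "simulate")
}

#' Default run configuration
#'
#' @return nested list mirroring the YAML configuration schema.
#' @export
default_config <- function() {
  list(seed = 1L,
       paths = list(images = "images", outputs = "outputs"),
       n_images = 2L,
       radiometry = list(gamma = 2.2, standard_value = 40),
       segmentation = list(window_px = 31, offset_pp = 5, min_spot_px = 9),
       lwm = list(k_neighbors = 6),
       ovometry = list(n_stations = 200),
       stats = list(responses = c("PC1", "PC2")),
       simulate = list(n_spots = 15, noise_sd = 40, traits = TRUE,
                       warp = list(style = "smooth_bumps", magnitude_px = 4)))
}

#' Read and validate a YAML run configuration
#'
#' Unknown top-level keys are rejected; a seed is mandatory; the standard
#' reflectance must lie in (0, 100].
#'
#' @param path YAML file path, or a list already in memory.
#' @return validated configuration list merged over the defaults.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown) > 0) stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("configuration must declare a seed")
  out <- utils::modifyList(default_config(), cfg)
  sv <- out$radiometry$standard_value
  if (sv <= 0 || sv > 100) stop("standard_value must be in (0, 100]")
  out$seed <- as.integer(out$seed)
  out
}

log_line <- function(logfile, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = logfile, append = TRUE)
}

write_image <- function(img, path) {
  mc <- 2^img$bit_depth - 1
  a <- simplify2array(img$bands) / mc   # h x w x bands in [0,1]
  if (length(dim(a)) == 3 && dim(a)[3] == 1) a <- a[, , 1]
  tiff::writeTIFF(a, path, bits.per.sample = 16L)
  invisible(path)
}

read_image <- function(path, bands) {
  a <- tiff::readTIFF(path)
  mc <- 2^16 - 1
  if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1))
  bl <- lapply(seq_along(bands), function(i) round(a[, , i] * mc))
  names(bl) <- bands
  raw_image(bl, bit_depth = 16L)
}

#' Generate a fixture directory of synthetic eggs
#'
#' Writes, under `paths$images`: per-egg VIS and UV 16-bit TIFFs with a JSON
#' truth sidecar each, the synthetic trait table CSV, and a manifest listing
#' every artifact with its MD5 checksum. Deterministic for a fixed seed.
#'
#' @param config configuration list or YAML path (see [read_config()]).
#' @param base_dir directory the configured paths are resolved against.
#' @param force overwrite an existing non-empty image directory.
#' @return invisibly, the manifest data.frame.
#' @export
cmd_simulate <- function(config, base_dir = ".", force = FALSE) {
  cfg <- read_config(config)
  dir_img <- file.path(base_dir, cfg$paths$images)
  if (dir.exists(dir_img) && length(dir(dir_img)) > 0 && !force) {
    stop("output directory is not empty (use force = TRUE to overwrite): ", dir_img)
  }
  dir.create(dir_img, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(dir_img, "simulate.log.jsonl")
  unlink(logfile)
  files <- character(0)

  n_img <- cfg$n_images %||% 0L
  for (i in seq_len(n_img)) {
    truth <- make_egg_image(n_spots = cfg$simulate$n_spots,
                            warp_params = cfg$simulate$warp,
                            gamma = cfg$radiometry$gamma,
                            noise_sd = cfg$simulate$noise_sd,
                            seed = cfg$seed + i)
    id <- sprintf("egg%03d", i)
    f_vis <- file.path(dir_img, paste0(id, "_vis.tif"))
    f_uv <- file.path(dir_img, paste0(id, "_uv.tif"))
    f_json <- file.path(dir_img, paste0(id, "_truth.json"))
    write_image(truth$vis_raw, f_vis)
    write_image(truth$uv_raw, f_uv)
    sidecar <- list(egg_id = id,
                    roi = unname(apply(truth$roi, 1, as.numeric, simplify = FALSE)),
                    standard_patch = list(
                      polygon = unname(apply(truth$standard_patch$polygon, 1, as.numeric,
                                             simplify = FALSE)),
                      polygon_uv = unname(apply(truth$standard_patch$polygon_uv, 1,
                                                as.numeric, simplify = FALSE)),
                      value = truth$standard_patch$value),
                    scale_bar = list(points = unname(apply(truth$scale_bar$points, 1,
                                                           as.numeric, simplify = FALSE)),
                                     known_mm = truth$scale_bar$known_mm),
                    control_points = truth$control_points,
                    gamma = truth$gamma, mm_per_px = truth$mm_per_px,
                    band_reflectance_truth = lapply(truth$band_reflectance_truth, as.list),
                    shape_truth = truth$shape_truth,
                    spottiness_truth_pct = truth$spottiness_truth_pct,
                    n_spots = length(truth$spot_radii),
                    seed = truth$seed)
    jsonlite::write_json(sidecar, f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f_vis, f_uv, f_json)
    log_line(logfile, "simulate", egg = id, n_spots = length(truth$spot_radii))
  }

  if (isTRUE(cfg$simulate$traits)) {
    traits <- make_trait_dataset(seed = cfg$seed)
    f_traits <- file.path(dir_img, "traits_truth.csv")
    utils::write.csv(traits$table, f_traits, row.names = FALSE)
    files <- c(files, f_traits)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = if (length(files) > 0) unname(tools::md5sum(files)) else character(0),
                         row.names = NULL)
  utils::write.csv(manifest, file.path(dir_img, "manifest.csv"), row.names = FALSE)
  log_line(logfile, "simulate", manifest = nrow(manifest))
  invisible(manifest)
}

#' Measure one egg through the full image pipeline
#'
#' radiometry (linearize + standard normalization) -> spot segmentation ->
#' morphometry -> LWM alignment and UV measurement. Eggs with fewer than 13
#' control points yield a flagged row with blank UV columns.
#'
#' @param vis_raw,uv_raw [raw_image()]s (UV may be NULL).
#' @param sidecar list with roi, standard_patch, scale_bar, control_points,
#'   gamma, as written by [cmd_simulate()].
#' @param cfg validated configuration.
#' @return one-row data.frame of the per-egg report.
#' @export
measure_egg <- function(vis_raw, uv_raw, sidecar, cfg = default_config()) {
  roi <- do.call(rbind, lapply(sidecar$roi, as.numeric))
  std_poly <- do.call(rbind, lapply(sidecar$standard_patch$polygon, as.numeric))
  std_poly_uv <- if (!is.null(sidecar$standard_patch$polygon_uv)) {
    do.call(rbind, lapply(sidecar$standard_patch$polygon_uv, as.numeric))
  } else std_poly
  scale_pts <- do.call(rbind, lapply(sidecar$scale_bar$points, as.numeric))
  gamma <- sidecar$gamma %||% cfg$radiometry$gamma

  vis_lin <- linearize(vis_raw, gamma)
  refl_vis <- to_reflectance(vis_lin, std_poly, sidecar$standard_patch$value)
  mask <- segment_spots(refl_vis, roi, cfg$segmentation)
  mm_per_px <- calibrate_scale(scale_pts, sidecar$scale_bar$known_mm)
  report <- NULL

  cp <- as.data.frame(sidecar$control_points)
  uv_ok <- !is.null(uv_raw) && nrow(cp) >= 13
  refl_uv_aligned <- NULL
  warped <- NULL
  if (uv_ok) {
    uv_lin <- linearize(uv_raw, gamma)
    refl_uv <- to_reflectance(uv_lin, std_poly_uv, sidecar$standard_patch$value)
    t_lwm <- fit_lwm(cp[, c("x_vis", "y_vis", "x_uv", "y_uv")],
                     k_neighbors = cfg$lwm$k_neighbors)
    warped <- warp_mask(mask, t_lwm, uv_shape = dim(refl_uv))
    uvm <- uv_measure(refl_uv, warped)
  }

  prof <- extract_profile(roi, mm_per_px, n_stations = cfg$ovometry$n_stations)
  metrics <- volume_surface(prof)

  rep_vis <- summarize_spots(refl_vis, NULL, mask, roi, mm_per_px,
                             egg_id = sidecar$egg_id %||% "egg")
  data.frame(egg = rep_vis$egg_id,
             spot_number = rep_vis$spot_number,
             spot_size = rep_vis$mean_spot_size_mm2,
             spottiness = rep_vis$spottiness_pct,
             B_VIS = rep_vis$B_VIS, S_VIS = rep_vis$S_VIS,
             B_UV = if (uv_ok) uvm$B_UV else NA_real_,
             S_UV = if (uv_ok) uvm$S_UV else NA_real_,
             B_VIS_R = rep_vis$B_VIS_bands[["R"]],
             B_VIS_G = rep_vis$B_VIS_bands[["G"]],
             B_VIS_B = rep_vis$B_VIS_bands[["B"]],
             S_VIS_R = rep_vis$S_VIS_bands[["R"]],
             S_VIS_G = rep_vis$S_VIS_bands[["G"]],
             S_VIS_B = rep_vis$S_VIS_bands[["B"]],
             volume_mm3 = metrics$volume_mm3,
             surface_mm2 = metrics$surface_mm2,
             sv_per_mm = metrics$sv_per_mm,
             mm_per_px = mm_per_px,
             flag = if (uv_ok) "" else "uv_unavailable",
             stringsAsFactors = FALSE)
}

#' Run the measurement stage over a fixture directory
#'
#' Walks `paths$images` for `*_vis.tif` / `*_uv.tif` / `*_truth.json`
#' triples and writes `egg_report.csv` under `paths$outputs`. Per-egg
#' failures are logged and flagged; the run continues.
#'
#' @inheritParams cmd_simulate
#' @return invisibly, the report data.frame.
#' @export
cmd_measure <- function(config, base_dir = ".") {
  cfg <- read_config(config)
  dir_img <- file.path(base_dir, cfg$paths$images)
  dir_out <- file.path(base_dir, cfg$paths$outputs)
  dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(dir_out, "measure.log.jsonl")
  unlink(logfile)
  vis_files <- sort(dir(dir_img, pattern = "_vis\\.tif$", full.names = TRUE))
  rows <- list()
  for (f in vis_files) {
    id <- sub("_vis\\.tif$", "", basename(f))
    f_uv <- file.path(dir_img, paste0(id, "_uv.tif"))
    f_json <- file.path(dir_img, paste0(id, "_truth.json"))
    if (!file.exists(f_json)) {
      log_line(logfile, "measure", egg = id, skipped = "missing sidecar")
      next
    }
    sidecar <- jsonlite::read_json(f_json, simplifyVector = TRUE)
    sidecar$roi <- as.list(as.data.frame(t(sidecar$roi)))
    sidecar$standard_patch$polygon <- as.list(as.data.frame(t(sidecar$standard_patch$polygon)))
    if (!is.null(sidecar$standard_patch$polygon_uv)) {
      sidecar$standard_patch$polygon_uv <- as.list(as.data.frame(t(sidecar$standard_patch$polygon_uv)))
    }
    sidecar$scale_bar$points <- as.list(as.data.frame(t(sidecar$scale_bar$points)))
    row <- tryCatch({
      vis_raw <- read_image(f, c("R", "G", "B"))
      uv_raw <- if (file.exists(f_uv)) read_image(f_uv, "UV") else NULL
      measure_egg(vis_raw, uv_raw, sidecar, cfg)
    }, error = function(e) {
      log_line(logfile, "measure", egg = id, error = conditionMessage(e))
      data.frame(egg = id, spot_number = NA_integer_, spot_size = NA_real_,
                 spottiness = NA_real_, B_VIS = NA_real_, S_VIS = NA_real_,
                 B_UV = NA_real_, S_UV = NA_real_,
                 B_VIS_R = NA_real_, B_VIS_G = NA_real_, B_VIS_B = NA_real_,
                 S_VIS_R = NA_real_, S_VIS_G = NA_real_, S_VIS_B = NA_real_,
                 volume_mm3 = NA_real_, surface_mm2 = NA_real_,
                 sv_per_mm = NA_real_, mm_per_px = NA_real_,
                 flag = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    rows[[id]] <- row
    log_line(logfile, "measure", egg = id,
             flag = row$flag[1])
  }
  report <- if (length(rows) > 0) do.call(rbind, rows) else
    measure_report_header()
  utils::write.csv(report, file.path(dir_out, "egg_report.csv"),
                   row.names = FALSE, na = "")
  invisible(report)
}

measure_report_header <- function() {
  data.frame(egg = character(0), spot_number = integer(0), spot_size = numeric(0),
             spottiness = numeric(0), B_VIS = numeric(0), S_VIS = numeric(0),
             B_UV = numeric(0), S_UV = numeric(0),
             B_VIS_R = numeric(0), B_VIS_G = numeric(0), B_VIS_B = numeric(0),
             S_VIS_R = numeric(0), S_VIS_G = numeric(0), S_VIS_B = numeric(0),
             volume_mm3 = numeric(0), surface_mm2 = numeric(0),
             sv_per_mm = numeric(0), mm_per_px = numeric(0), flag = character(0),
             stringsAsFactors = FALSE)
}

#' Run the statistical stage on a trait table
#'
#' If the seven trait columns are present the table is log-transformed and
#' scored by correlation-matrix PCA (writing the loading report); otherwise
#' the existing PC1/PC2 columns are used directly. The model-selection
#' workflow then writes one comparison CSV per stage and response plus a
#' JSON fit audit.
#'
#' @param config configuration list or YAML path.
#' @param traits trait table data.frame, or NULL to read
#'   `<images>/traits_truth.csv`.
#' @inheritParams cmd_simulate
#' @return invisibly, a list of the comparison objects per response.
#' @export
cmd_analyze <- function(config, base_dir = ".", traits = NULL) {
  cfg <- read_config(config)
  dir_out <- file.path(base_dir, cfg$paths$outputs)
  dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(dir_out, "analyze.log.jsonl")
  unlink(logfile)
  if (is.null(traits)) {
    f <- file.path(base_dir, cfg$paths$images, "traits_truth.csv")
    if (!file.exists(f)) stop("no trait table found at ", f)
    traits <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  if (all(trait_names() %in% names(traits))) {
    lt <- log_traits(traits)
    if (nrow(lt) < 8) stop("PCA requires at least 8 rows")
    pca <- pca_corr(lt)
    utils::write.csv(cbind(trait = rownames(pca$loadings),
                           as.data.frame(round(pca$loadings[, 1:2], 4)),
                           variance_fraction_PC1 = pca$variance_fraction[1],
                           variance_fraction_PC2 = pca$variance_fraction[2]),
                     file.path(dir_out, "pca_loadings.csv"), row.names = FALSE)
    traits$PC1 <- NA_real_; traits$PC2 <- NA_real_
    traits$PC1[pca$complete] <- pca$scores[, 1]
    traits$PC2[pca$complete] <- pca$scores[, 2]
    traits <- traits[pca$complete, ]
    log_line(logfile, "pca", n = pca$n,
             var_pc1 = pca$variance_fraction[1], var_pc2 = pca$variance_fraction[2])
  }
  out <- list()
  audits <- list()
  for (resp in cfg$stats$responses) {
    sel <- run_selection(traits, resp)
    out[[resp]] <- sel
    utils::write.csv(sel$spatio_temporal$table,
                     file.path(dir_out, sprintf("spatio_temporal_%s.csv", resp)),
                     row.names = FALSE)
    utils::write.csv(sel$environmental$table,
                     file.path(dir_out, sprintf("environmental_%s.csv", resp)),
                     row.names = FALSE)
    audits[[resp]] <- list(
      random_effect = sel$random_effect,
      models = lapply(c(sel$spatio_temporal$models, sel$environmental$models),
                      function(m) list(label = m$label, criterion = m$criterion,
                                       k = m$k, n = m$n, loglik = m$loglik,
                                       coefficients = m$coefficients,
                                       sigma2_alpha = m$sigma2_alpha,
                                       sigma2_eps = m$sigma2_eps,
                                       edf = m$edf)))
    log_line(logfile, "selection", response = resp, seed = cfg$seed,
             best_st = sel$spatio_temporal$table$label[sel$spatio_temporal$table$best],
             best_env = sel$environmental$table$label[sel$environmental$table$best])
  }
  jsonlite::write_json(audits, file.path(dir_out, "fit_audit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(out)
}
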