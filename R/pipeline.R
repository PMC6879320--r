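#' Package defaults
#'
#' All tunable analysis defaults in one inspectable list (written to
#' `defaults.yaml` by [write_defaults()]): every methodological choice is
#' a parameter, never a hard-coded constant.
#'
#' @return Named list of defaults.
#' @export
package_defaults <- function() {
  list(
    pixel_size_um = 0.0977,
    intensity_threshold = 0,
    smoothing_window = 3,
    monomer_anisotropy = 0.23,
    bleach = list(n_bins = 10, fit_range = c(0.2, 1)),
    fcs = list(s = 0.2, lag_range = c(5e-6, 2), lags_per_octave = 16,
               qc = list(drift_frac = 0.1, k_sd = 5, window_s = 0.1),
               bounds = list(tau_d1 = c(3e-4, 3e-3), tau_d2 = c(1e-2, 0.2))),
    laurdan = list(gp_ref = 0.207),
    blobs = list(sigma = 1, min_size = 4, use_gradient = FALSE),
    pattern = list(spacing_um = 2, width_nm = 100,
                   on_roi_um = c(1, 4), inter_roi_um = c(2, 2)),
    spreading = list(frame_interval_s = 15, drop_lead_s = 150)
  )
}

#' @rdname package_defaults
#' @param path output YAML path.
#' @export
write_defaults <- function(path = "defaults.yaml") {
  yaml::write_yaml(package_defaults(), path)
  invisible(path)
}

pipeline_schema <- list(
  stage = c("aniso", "gp", "fcs", "bleach"),
  keys = list(
    common = c("stage", "seed", "out_dir"),
    aniso = c("pa_tiff", "pe_tiff", "background", "gfactor", "threshold",
              "smoothing_window", "pixel_size_um", "synthetic"),
    gp = c("ch1_tiff", "ch2_tiff", "gp_mes", "gp_ref", "threshold",
           "synthetic"),
    fcs = c("acf_csv", "fix_s", "synthetic"),
    bleach = c("pa_tiff", "pe_tiff", "gfactor", "n_bins", "rois",
               "synthetic")))

validate_config <- function(config) {
  if (is.null(config$stage) || !config$stage %in% pipeline_schema$stage)
    stop("config key 'stage' must be one of: ",
         paste(pipeline_schema$stage, collapse = ", "))
  allowed <- c(pipeline_schema$keys$common,
               pipeline_schema$keys[[config$stage]])
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("unknown config key(s) for stage '", config$stage, "': ",
         paste(bad, collapse = ", "))
  invisible(config)
}

#' Run an analysis pipeline from a config
#'
#' Executes one analysis stage described by a YAML-style config list and
#' writes its outputs plus a `RunManifest` (config snapshot, input
#' digests, package version, seed, timestamps) into `out_dir`. The config
#' is validated against the stage schema before any computation; inputs
#' are never modified; re-running the same config and seed reproduces
#' deterministic outputs bit-identically.
#'
#' Stages: `aniso` (anisotropy map + ROI-free pixel CSV), `gp` (GP map),
#' `fcs` (model fit of an ACF CSV), `bleach` (bleach curve). Each stage
#' accepts `synthetic: true` to run on a built-in generator scene, which
#' makes the pipeline runnable end-to-end without data.
#'
#' @param config named list (e.g. `yaml::read_yaml(path)`).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  outputs <- character(0)
  if (config$stage == "aniso") {
    set <- if (isTRUE(config$synthetic)) {
      make_polarized_scene(r_field = 0.2, intensity = 300, seed = seed)
    } else {
      read_polarized_tiff(config$pa_tiff, config$pe_tiff,
                          pixel_size = config$pixel_size_um %||% 0.0977,
                          background_ipa = config$background %||% 0,
                          background_ipe = config$background %||% 0)
    }
    set <- subtract_background(set)
    g <- gfactor_field(config$gfactor %||% 1)
    amap <- compute_anisotropy(set, g,
                               threshold = config$threshold %||% 0,
                               smoothing_window =
                                 config$smoothing_window %||% 1)
    f1 <- file.path(out_dir, "anisotropy.tif")
    f2 <- file.path(out_dir, "total_intensity.tif")
    f3 <- file.path(out_dir, "anisotropy_summary.csv")
    write_float_tiff(amap$r_smooth, f1)
    write_float_tiff(amap$total_intensity, f2)
    write_stats_csv(data.frame(
      n_pixels = sum(amap$mask),
      mean_r = mean(amap$r, na.rm = TRUE),
      sd_r = stats::sd(amap$r, na.rm = TRUE),
      mean_total = mean(amap$total_intensity[amap$mask])), f3)
    outputs <- c(f1, f2, f3)
  } else if (config$stage == "gp") {
    sc <- if (isTRUE(config$synthetic)) {
      make_gp_scene(gp_field = 0.3, seed = seed)
    } else {
      list(ch1 = read_tiff_stack(config$ch1_tiff)[, , 1],
           ch2 = read_tiff_stack(config$ch2_tiff)[, , 1])
    }
    cal <- calibrate_gfactor(config$gp_mes %||% 0.207,
                             config$gp_ref %||% 0.207)
    gpm <- compute_gp(sc$ch1, sc$ch2, cal,
                      threshold = config$threshold %||% 0)
    f1 <- file.path(out_dir, "gp_map.tif")
    write_float_tiff(gpm$gp, f1)
    outputs <- f1
  } else if (config$stage == "fcs") {
    curve <- if (isTRUE(config$synthetic)) {
      make_fcs_curve(fcs_params(), seed = seed)
    } else read_acf_csv(config$acf_csv)
    free <- c("n", "t_dark", "tau_t", "f", "tau_d1", "tau_d2")
    if (identical(config$fix_s, FALSE)) free <- c(free, "s")
    fit <- fit_acf(curve, free = free)
    f1 <- file.path(out_dir, "fcs_fit.json")
    jsonlite::write_json(list(params = unclass(fit$params),
                              se = as.list(fit$se), rss = fit$rss,
                              converged = fit$converged),
                         f1, auto_unbox = TRUE, digits = NA)
    f2 <- file.path(out_dir, "fcs_fitted_curve.csv")
    write_stats_csv(data.frame(lag_s = fit$lags, G = fit$fitted), f2)
    outputs <- c(f1, f2)
  } else if (config$stage == "bleach") {
    series <- if (isTRUE(config$synthetic)) {
      make_bleach_series(poisson = TRUE, read_noise_sd = 2, seed = seed)
    } else {
      read_polarized_tiff(config$pa_tiff, config$pe_tiff)
    }
    rois <- default_grid_rois(dim(series$ipa)[1:2], n = 9, size = 16)
    bc <- bleach_analysis(series, gfactor_field(config$gfactor %||% 1),
                          rois, n_bins = config$n_bins %||% 10)
    f1 <- file.path(out_dir, "bleach_curve.csv")
    write_stats_csv(bc, f1)
    outputs <- f1
  }
  manifest <- list(
    package = "ndimg",
    version = as.character(utils::packageVersion("ndimg")),
    stage = config$stage, seed = seed, config = config,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Evenly spaced square ROIs over the central part of an image.
default_grid_rois <- function(dims, n = 9, size = 16) {
  k <- ceiling(sqrt(n))
  xs <- round(seq(1, dims[2] - size, length.out = k))
  ys <- round(seq(1, dims[1] - size, length.out = k))
  rois <- list()
  for (y in ys) for (x in xs) {
    if (length(rois) < n)
      rois[[length(rois) + 1]] <- region_rect(x, y, size, size)
  }
  rois
}
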