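#' Convert a segmented soma area from pixels to square micrometers
#'
#' Uses the raster calibration
#' `um/pixel = 291.2 um/deg * axial_length / 24.2 mm * FOV_width / 496 px`
#' and squares the scale.
#'
#' @param area_px2 Area in pixels squared.
#' @param axial_length_mm Axial length of the eye, mm.
#' @param fov_width_deg Imaging field-of-view width, deg.
#' @param raster_width_px Raster width in pixels (496 for the imaging PMT).
#' @return Area in square micrometers.
#' @examples
#' pixel_area_to_um2(100, 17.2, 3.64)
#' @export
pixel_area_to_um2 <- function(area_px2, axial_length_mm, fov_width_deg,
                              raster_width_px = 496) {
  if (any(c(area_px2, axial_length_mm, fov_width_deg, raster_width_px) <= 0)) {
    stop("all inputs must be positive.", call. = FALSE)
  }
  scale <- 291.2 * axial_length_mm / 24.2 * fov_width_deg / raster_width_px
  area_px2 * scale^2
}

#' Default pipeline configuration
#'
#' All defaults mirror the stimulation and modeling conditions: 6.7 mm
#' pupil, 561 nm, 25.3 Hz refresh / 666 ms, peak density 270,200 cones/mm^2
#' with L:M:S 0.48:0.48:0.04, 0.067 D canonical residual defocus, 512
#' optimizer starts. `mosaic_extent_deg` and `n_starts` are the main knobs
#' for runtime.
#'
#' @param ... Named overrides of any default field.
#' @return A validated named list of class `stf_config`.
#' @export
stf_config <- function(...) {
  cfg <- list(
    axial_length_mm = 16.56,
    pupil_diameter_mm = 6.7,
    wavelength_nm = 561,
    defocus_D = 0.067,
    mosaic_extent_deg = 0.3,
    peak_density_mm2 = 270200,
    class_fractions = c(L = 0.48, M = 0.48, S = 0.04),
    mosaic_seed = 1,
    frequencies = default_stf_frequencies(),
    scenario = "single-cone",
    n_starts = 512,
    fit_seed = 1,
    truth = list(kc = 1.5, ks = 0.25, rs_deg = 0.05,
                 scenario = "single-cone"),
    sessions = 3,
    noise_frac = 0.10,
    data_seed = 1,
    physio_blur_deg = 0.015,
    output_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "stf_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [stf_config()] defaults.
#'
#' @param path YAML file path.
#' @return An `stf_config`.
#' @export
read_stf_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$class_fractions)) y$class_fractions <- unlist(y$class_fractions)
  if (!is.null(y$frequencies)) y$frequencies <- as.numeric(y$frequencies)
  do.call(stf_config, y)
}

#' Run the end-to-end STF modeling pipeline on synthetic data
#'
#' Executes the full chain: mosaic synthesis, optics, forward-model context,
#' synthetic multi-session STF generation from the configured ground truth,
#' DoG fitting, derived statistics, and the physiological-optics prediction.
#' All stages are seeded; rerunning an identical config reproduces every
#' number. When `output_dir` is set, tables are written as TSV along with a
#' YAML run log recording seeds and stage timings.
#'
#' @param config An [stf_config()].
#' @return A list of class `stf_run`: `mosaic`, `optics`, `context`,
#'   `dataset`, `fit`, `stats`, `physio`, `config`, `log`.
#' @export
run_stf_pipeline <- function(config = stf_config()) {
  stopifnot(inherits(config, "stf_config"))
  log <- list(started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              seeds = list(mosaic = config$mosaic_seed,
                           data = config$data_seed,
                           fit = config$fit_seed))
  tic <- function() Sys.time()
  stage <- function(nm, expr) {
    t0 <- tic()
    val <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE)
    })
    log$timing[[nm]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    val
  }
  geometry <- eye_geometry(config$axial_length_mm)
  mosaic <- stage("mosaic", synthesize_cone_mosaic(
    peak_density_mm2 = config$peak_density_mm2,
    extent_deg = config$mosaic_extent_deg,
    class_fractions = config$class_fractions,
    geometry = geometry, seed = config$mosaic_seed))
  optics <- stage("optics", compute_psf_mtf(
    pupil_spec(config$pupil_diameter_mm, config$wavelength_nm,
               config$defocus_D), geometry))
  context <- stage("context", stf_model_context(
    mosaic, optics, frequencies = config$frequencies))
  truth <- stage("truth", do.call(build_rf_weights, c(
    list(mosaic = mosaic), config$truth)))
  dataset <- stage("synthesis", synth_stf_dataset(
    truth, context, sessions = config$sessions,
    noise_frac = config$noise_frac, seed = config$data_seed))
  fit <- stage("fit", fit_stf(
    dataset$averaged, context, scenario = config$scenario,
    candidate_positions = matrix(truth$center_deg, 1),
    n_starts = config$n_starts, seed = config$fit_seed))
  stats <- stage("stats", derived_stats(fit))
  physio <- stage("physio", predict_physiological_stf(
    fit, gaussian_optics(config$physio_blur_deg), context))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_mosaic(mosaic, file.path(config$output_dir, "mosaic.tsv"))
    readr::write_tsv(dataset$averaged,
                     file.path(config$output_dir, "measured_stf.tsv"))
    readr::write_tsv(tidy(fit), file.path(config$output_dir, "fit.tsv"))
    readr::write_tsv(stats, file.path(config$output_dir, "derived_stats.tsv"))
    readr::write_tsv(physio$stf,
                     file.path(config$output_dir, "physio_stf.tsv"))
    writeLines(yaml::as.yaml(c(log, list(config = unclass_config(config)))),
               file.path(config$output_dir, "run_log.yaml"))
  }
  structure(list(mosaic = mosaic, optics = optics, context = context,
                 dataset = dataset, fit = fit, stats = stats,
                 physio = physio, config = config, log = log),
            class = "stf_run")
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$class_fractions <- as.list(out$class_fractions)
  out$frequencies <- as.numeric(out$frequencies)
  out
}

#' @export
print.stf_run <- function(x, ...) {
  cat("<stf_run>\n")
  cat("  mosaic:", nrow(x$mosaic), "cones over",
      attr(x$mosaic, "extent_deg"), "deg\n")
  cat("  scenario:", x$fit$scenario, " defocus:", x$fit$defocus_D, "D\n")
  cat(sprintf("  fit: kc=%.3g ks=%.3g rs=%.4g deg rmse=%.3g\n",
              x$fit$kc, x$fit$ks, x$fit$rs_deg, x$fit$rmse))
  invisible(x)
}
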