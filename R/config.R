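#' Default run configuration
#'
#' All tunable parameters of the pipeline, with defaults matching the
#' published parameterization of the tracker: estimated patch diameter
#' 0.6 um, detection threshold = 0.32 x mean probe intensity in the
#' presynaptic area, linking max distance 0.5 um, no gap closing, minimum
#' 4 detections per track, rolling-ball radius 50 px, 256-bin histograms
#' for automatic thresholding.
#'
#' @param ... Named overrides. Top-level keys: `pixel_size_um`,
#'   `frame_interval_s`, `rng_seed`, and the nested blocks `detection`,
#'   `tracking`, `preprocess`, `cov`, `calibration`. Nested overrides are
#'   merged key-wise, e.g. `detection = list(threshold_factor = 0.5)`.
#' @return A `patch_config` (nested named list).
#' @examples
#' cfg <- patch_config(rng_seed = 7, tracking = list(min_spots = 3))
#' cfg$tracking$min_spots
#' @export
patch_config <- function(...) {
  defaults <- list(
    pixel_size_um = 0.13,
    frame_interval_s = 4,
    rng_seed = 1L,
    detection = list(
      diameter_um = 0.6,
      threshold_factor = 0.32,
      # "quality" thresholds the contrast-calibrated LoG response (the
      # detector's native score); "intensity" thresholds the raw
      # disc-aggregated peak intensity instead. See the methods vignette
      # for why quality is the usable default on diffuse-baseline signal.
      threshold_on = "quality",
      median_filter = FALSE,
      subpixel = TRUE
    ),
    tracking = list(
      linking_max_um = 0.5,
      gap_frames = 0L,
      min_spots = 4L,
      # patches are stationary structures: tracks whose median per-frame
      # step exceeds this are tracking defects (e.g. noise wandering
      # along an intensity ridge), not patches. Default half the spot
      # radius; NULL disables.
      max_median_step_um = 0.15,
      # "shorter": of two conflicting concurrent tracks drop the shorter;
      # "both": drop both.
      overlap_policy = "shorter"
    ),
    preprocess = list(
      register = FALSE,
      max_shift_px = 5,
      rolling_ball_radius_px = 50,
      blur_sigma_px = 2,
      mask_method = "otsu",
      keep_largest = FALSE,
      cov_on_subtracted = FALSE
    ),
    cov = list(
      n_bins = 256L
    ),
    calibration = list(
      multipliers = c(0.5, 0.75, 1, 1.25, 1.5, 2),
      n_reps = 10L,
      statistic = "mean_cov"
    )
  )
  cfg <- merge_config(defaults, list(...), warn_unknown = TRUE)
  validate_config(cfg)
  structure(cfg, class = "patch_config")
}

merge_config <- function(base, override, warn_unknown = FALSE, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base)) {
      if (warn_unknown) {
        warning(sprintf("unknown config key ignored: %s%s", path, key),
                call. = FALSE)
      }
      next
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  warn_unknown, paste0(path, key, "$"))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  assert_scalar_num(cfg$pixel_size_um, "pixel_size_um", positive = TRUE)
  assert_scalar_num(cfg$frame_interval_s, "frame_interval_s", positive = TRUE)
  assert_scalar_num(cfg$detection$diameter_um, "detection$diameter_um",
                    positive = TRUE)
  assert_scalar_num(cfg$detection$threshold_factor,
                    "detection$threshold_factor", positive = TRUE)
  if (!cfg$detection$threshold_on %in% c("quality", "intensity")) {
    abort_ap("detection$threshold_on must be 'quality' or 'intensity'")
  }
  assert_scalar_num(cfg$tracking$linking_max_um, "tracking$linking_max_um",
                    positive = TRUE)
  assert_scalar_num(cfg$tracking$min_spots, "tracking$min_spots",
                    positive = TRUE)
  if (!cfg$tracking$overlap_policy %in% c("shorter", "both")) {
    abort_ap("tracking$overlap_policy must be 'shorter' or 'both'")
  }
  assert_scalar_num(cfg$preprocess$rolling_ball_radius_px,
                    "preprocess$rolling_ball_radius_px", positive = TRUE)
  assert_scalar_num(cfg$cov$n_bins, "cov$n_bins", positive = TRUE)
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Absent keys take the documented defaults of [patch_config()]; unknown
#' keys raise a warning; invalid values (e.g. a non-positive pixel size)
#' are an error.
#'
#' @param path Path to a YAML file (flat keys plus nested blocks).
#' @return A `patch_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_ap("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(patch_config, vals)
}
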