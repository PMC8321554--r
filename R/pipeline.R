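#' Run the full patch-dynamics pipeline on one movie
#'
#' Orchestrates the analysis stages in their standard order --
#' (registration) -> mask -> detection -> linking -> filtering -> patch
#' statistics -> CoV statistics -- and returns every intermediate plus a
#' manifest that makes the run reproducible (config snapshot, seed,
#' package version). Identical config + input give identical output.
#'
#' @param movie A [patch_movie()], or a [synthetic_spec()] to simulate
#'   first.
#' @param config A [patch_config()].
#' @param mask Optional [patch_mask()]; computed from the movie with the
#'   configured method when absent (for simulated input the ground-truth
#'   geometry is used).
#' @return A `patch_run` list: `movie, mask, spots, tracks, filtered,
#'   stats, cov, manifest` (and `truth` for simulated input).
#' @export
run_patch_pipeline <- function(movie, config = patch_config(),
                               mask = NULL) {
  truth <- NULL
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_ap("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if (inherits(movie, "synthetic_spec")) {
    sim <- stage("simulate", simulate_movie(movie))
    truth <- sim$truth
    if (is.null(mask)) mask <- sim$mask
    movie <- sim$movie
  }
  stopifnot(inherits(movie, "patch_movie"))
  if (isTRUE(config$preprocess$register)) {
    movie <- stage("register",
                   register_translation(movie,
                                        config$preprocess$max_shift_px)$movie)
  }
  if (is.null(mask)) {
    mask <- stage("mask",
                  make_presynaptic_mask(movie,
                                        config$preprocess$blur_sigma_px,
                                        config$preprocess$mask_method,
                                        config$preprocess$keep_largest))
  }
  spots <- stage("detect", detect_movie_spots(movie, mask,
                                              config$detection))
  tracks <- stage("link", link_tracks(spots, config$tracking))
  filtered <- stage("filter",
                    filter_tracks(tracks, config$tracking,
                                  movie$frame_interval_s, n_frames(movie)))
  stats <- stage("stats", patch_stats(filtered, movie, mask))
  cov <- stage("cov", cov_map(movie, mask))
  manifest <- list(
    package_version = as.character(utils::packageVersion("actinpatches")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    n_frames = n_frames(movie),
    mask_area_um2 = mask$area_um2,
    timestamp = NA_character_  # left NA: runs must be byte-reproducible
  )
  structure(
    list(movie = movie, mask = mask, spots = spots, tracks = tracks,
         filtered = filtered, stats = stats, cov = cov, truth = truth,
         manifest = manifest),
    class = "patch_run"
  )
}

#' @export
print.patch_run <- function(x, ...) {
  cat("<patch_run>\n")
  print(x$stats)
  print(x$cov)
  invisible(x)
}

#' Compare patch statistics between two groups of movies
#'
#' Group means with standard errors for the headline metrics, and the
#' percent difference of group means
#' (`100 * (mean_test / mean_control - 1)`), the hand-off point for
#' external hypothesis testing (no tests are run here).
#'
#' @param stats_control,stats_test Lists of `patch_stats` (one per
#'   movie/NMJ).
#' @return List with `summary` (per-group mean +/- sem and percent
#'   difference per metric) and `per_movie` (the raw per-movie table).
#' @export
compare_groups <- function(stats_control, stats_test) {
  if (length(stats_control) == 0 || length(stats_test) == 0) {
    abort_ap("both groups need >= 1 movie")
  }
  row_of <- function(s, group, i) {
    tibble::tibble(group = group, movie = i,
                   frequency = s$frequency_per10um2_min,
                   mean_duration_s = s$mean_duration_s,
                   mean_amplitude = s$mean_amplitude)
  }
  per_movie <- dplyr::bind_rows(
    purrr::imap_dfr(stats_control, ~row_of(.x, "control", .y)),
    purrr::imap_dfr(stats_test, ~row_of(.x, "test", .y)))
  long <- tidyr::pivot_longer(per_movie, c("frequency", "mean_duration_s",
                                           "mean_amplitude"),
                              names_to = "metric")
  summary <- long |>
    dplyr::group_by(.data$metric, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("mean", "sem", "n")) |>
    dplyr::mutate(percent_difference =
                    100 * (.data$mean_test / .data$mean_control - 1))
  list(summary = summary, per_movie = per_movie)
}
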