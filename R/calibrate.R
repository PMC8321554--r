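cov_statistic <- function(sim, statistic, n_bins = 256L) {
  cv <- cov_map(sim$movie, sim$mask)
  switch(statistic,
         mean_cov = cv$mean_cov,
         variant_fraction_li = variant_area_fraction(cv, "li", n_bins),
         abort_ap("unknown calibration statistic '%s'", statistic))
}

#' Build a CoV-vs-frequency calibration curve by simulation
#'
#' For each frequency multiplier `m`, simulates `n_reps` movies from the
#' base spec with `event_frequency = m * f0`, computes the chosen CoV
#' statistic per movie, and fits a monotone map multiplier -> statistic
#' (isotonic regression of the per-multiplier means, then a monotone
#' Hermite cubic interpolant -- the statistic's response is concave in
#' frequency, which a piecewise-linear chord would systematically
#' undershoot between knots, biasing the inversion). This is the forward model that lets a measured
#' CoV difference between genotypes be read back as a patch-frequency
#' change. The base spec must match the experiment's imaging regime
#' (frame interval, movie length, noise); a curve is never reused across
#' regimes.
#'
#' Within each replicate, the multipliers share common random numbers:
#' one master event stream is drawn at the largest multiplier and thinned
#' to each `m` (keeping events whose uniform mark is below `m / m_max`,
#' which is marginally an exact draw at rate `m * f0`), and the same
#' noise seed is reused. This nested coupling cancels most of the
#' between-multiplier simulation noise, so the curve's local slopes --
#' what the inversion in [infer_frequency_change()] relies on -- are far
#' better determined than with independent draws.
#'
#' @param base_spec A [synthetic_spec()].
#' @param multipliers Sorted frequency scale factors, must include 1 and
#'   have >= 3 entries.
#' @param n_reps Replicate simulations per multiplier (>= 3).
#' @param seed Integer seed.
#' @param statistic `"mean_cov"` (default) or `"variant_fraction_li"`.
#' @return A `calibration_curve` with the per-multiplier table and the
#'   interpolants.
#' @export
build_calibration_curve <- function(base_spec,
                                    multipliers = c(0.5, 0.75, 1, 1.25,
                                                    1.5, 2),
                                    n_reps = 10L, seed = 1L,
                                    statistic = "mean_cov") {
  if (length(multipliers) < 3) abort_ap("need >= 3 multipliers")
  if (is.unsorted(multipliers, strictly = TRUE)) {
    abort_ap("multipliers must be strictly increasing")
  }
  if (!any(abs(multipliers - 1) < 1e-12)) {
    abort_ap("multipliers must include 1.0")
  }
  if (n_reps < 3) abort_ap("need n_reps >= 3")
  m_max <- max(multipliers)
  mask <- make_geometry(base_spec)
  stat_mat <- vapply(seq_len(n_reps), function(r) {
    master_seed <- derive_seed(seed, r)
    sp_max <- base_spec
    sp_max$event_frequency <- m_max * base_spec$event_frequency
    ev_max <- sample_events(sp_max, mask,
                            seed = derive_seed(master_seed, 1L))
    marks <- with_seed(derive_seed(master_seed, 5L),
                       stats::runif(nrow(ev_max)))
    vapply(multipliers, function(m) {
      ev <- ev_max[marks <= m / m_max, , drop = FALSE]
      sp <- base_spec
      sp$event_frequency <- m * base_spec$event_frequency
      clean <- render_movie(ev, mask, sp)
      noisy <- apply_noise_and_bleach(clean, sp,
                                      seed = derive_seed(master_seed, 2L))
      cov_statistic(list(movie = noisy, mask = mask), statistic)
    }, numeric(1))
  }, numeric(length(multipliers)))
  stat_mat <- matrix(stat_mat, nrow = length(multipliers))
  rows <- tibble::tibble(
    multiplier = multipliers,
    statistic = rowMeans(stat_mat),
    se = apply(stat_mat, 1, stats::sd) / sqrt(n_reps),
    n_reps = n_reps)
  iso <- stats::isoreg(rows$multiplier, rows$statistic)
  fitted <- iso$yf
  if (is.unsorted(fitted, strictly = TRUE)) {
    abort_ap(paste("statistic is not strictly increasing in frequency",
                   "after isotonic adjustment; the base spec is",
                   "degenerate (e.g. noise-dominated)"))
  }
  fwd <- stats::splinefun(rows$multiplier, fitted, method = "monoH.FC")
  m_rng <- range(rows$multiplier)
  inv <- function(s) {
    vapply(s, function(si) {
      stats::uniroot(function(m) fwd(m) - si, interval = m_rng,
                     tol = 1e-10)$root
    }, numeric(1))
  }
  structure(
    list(table = dplyr::mutate(rows, fitted = fitted),
         statistic = statistic,
         base_frequency = base_spec$event_frequency,
         forward = fwd,
         inverse = inv,
         range = range(fitted)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s over multipliers [%.2g, %.2g] of f = %.2g /10um^2/min\n",
    x$statistic, min(x$table$multiplier), max(x$table$multiplier),
    x$base_frequency))
  print(x$table)
  invisible(x)
}

#' Infer a patch-frequency change from two CoV statistics
#'
#' Inverts the monotone calibration interpolant at the control and test
#' statistics and reports `100 * (m_test / m_control - 1)`, the percent
#' change in patch frequency consistent with the measured CoV
#' difference. Statistics outside the calibrated range are clamped to
#' the range edge with a warning (or rejected with `clamp = FALSE`).
#'
#' @param curve A `calibration_curve`.
#' @param stat_control,stat_test The measured statistic per group.
#' @param clamp Clamp out-of-range statistics to the curve edge?
#' @return Tibble `m_control, m_test, percent_change`.
#' @export
infer_frequency_change <- function(curve, stat_control, stat_test,
                                   clamp = TRUE) {
  clip <- function(s, name) {
    if (s < curve$range[1] || s > curve$range[2]) {
      if (!clamp) {
        abort_ap("%s = %.4g outside calibrated range [%.4g, %.4g]",
                 name, s, curve$range[1], curve$range[2])
      }
      warning(sprintf("%s outside calibrated range; clamped", name),
              call. = FALSE)
      s <- max(curve$range[1], min(curve$range[2], s))
    }
    s
  }
  m_c <- curve$inverse(clip(stat_control, "stat_control"))
  m_t <- curve$inverse(clip(stat_test, "stat_test"))
  tibble::tibble(m_control = m_c, m_test = m_t,
                 percent_change = 100 * (m_t / m_c - 1))
}

#' Tracking-parameter robustness sweep
#'
#' Re-runs detection + linking + filtering + frequency over a grid of
#' intensity-threshold factors and linking distances, quantifying how
#' robust a frequency (or a between-genotype difference) is to the
#' tracker parameterization.
#'
#' @param movie A [patch_movie()].
#' @param mask A [patch_mask()].
#' @param threshold_factors Grid of detection threshold factors.
#' @param link_distances_um Grid of linking max distances (um).
#' @param config A [patch_config()] supplying all other parameters.
#' @return Tibble `threshold_factor, linking_max_um, n_spots, n_tracks,
#'   frequency`. Detected spot counts (`n_spots`) are non-increasing in
#'   the threshold factor; accepted-track counts can invert locally
#'   (removing spots may split a long track into two accepted
#'   fragments), which is itself part of what the sweep exposes.
#' @export
parameter_robustness_sweep <- function(movie, mask,
                                       threshold_factors,
                                       link_distances_um,
                                       config = patch_config()) {
  if (length(threshold_factors) == 0 || length(link_distances_um) == 0) {
    abort_ap("parameter grids must be non-empty")
  }
  dur_min <- n_frames(movie) * movie$frame_interval_s / 60
  grid <- tidyr::expand_grid(threshold_factor = threshold_factors,
                             linking_max_um = link_distances_um)
  purrr::pmap_dfr(grid, function(threshold_factor, linking_max_um) {
    det <- config$detection
    det$threshold_factor <- threshold_factor
    trk <- config$tracking
    trk$linking_max_um <- linking_max_um
    spots <- detect_movie_spots(movie, mask, det)
    filt <- filter_tracks(link_tracks(spots, trk), trk,
                          movie$frame_interval_s, n_frames(movie))
    n_acc <- filt$report$n[filt$report$reason == "accepted"]
    tibble::tibble(threshold_factor = threshold_factor,
                   linking_max_um = linking_max_um,
                   n_spots = nrow(spots),
                   n_tracks = n_acc,
                   frequency = patch_frequency(n_acc, mask$area_um2,
                                               dur_min))
  })
}
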