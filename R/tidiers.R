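#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-track statistics of a movie
#'
#' @param x A `patch_stats` object.
#' @param ... Unused.
#' @return The duration histogram tibble (`bin_lo, bin_hi, center, count,
#'   freq`).
#' @export
tidy.patch_stats <- function(x, ...) x$duration_hist

#' One-row summary of a movie's patch statistics
#'
#' @param x A `patch_stats` object.
#' @param ... Unused.
#' @export
glance.patch_stats <- function(x, ...) {
  tibble::tibble(
    n_tracks = x$n_tracks,
    frequency_per10um2_min = x$frequency_per10um2_min,
    mean_duration_s = x$mean_duration_s,
    sd_duration_s = x$sd_duration_s,
    mean_amplitude = x$mean_amplitude,
    sd_amplitude = x$sd_amplitude,
    n_rejected_too_short = x$report$n[x$report$reason == "too_short"],
    n_rejected_overlap = x$report$n[x$report$reason == "overlap"],
    mask_area_um2 = x$mask_area_um2,
    movie_duration_min = x$movie_duration_min)
}

#' Tidy a CoV map into a per-pixel tibble
#'
#' @param x A `cov_result`.
#' @param ... Unused.
#' @return Tibble `row, col, cov` over masked pixels.
#' @export
tidy.cov_result <- function(x, ...) {
  idx <- which(x$mask$pixels, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2],
                 cov = x$cov_map[idx])
}

#' One-row summary of a CoV analysis
#'
#' @param x A `cov_result`.
#' @param ... Unused.
#' @export
glance.cov_result <- function(x, ...) {
  tibble::tibble(
    mean_cov = x$mean_cov,
    n_valid = x$n_valid,
    variant_fraction_li = variant_area_fraction(x, "li"),
    variant_fraction_moments = variant_area_fraction(x, "moments"))
}

#' @export
tidy.calibration_curve <- function(x, ...) x$table

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(statistic = x$statistic,
                 base_frequency = x$base_frequency,
                 n_multipliers = nrow(x$table),
                 stat_min = x$range[1], stat_max = x$range[2])
}

#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(term = c("tau_s", "mobile_fraction", "plateau", "n0"),
                 estimate = c(x$tau_s, x$mobile_fraction, x$plateau,
                              x$n0))
}

#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(tau_s = x$tau_s, mobile_fraction = x$mobile_fraction,
                 plateau = x$plateau, residual_rms = x$residual_rms,
                 flag = x$flag)
}

#' Plot a duration histogram
#'
#' @param object A `patch_stats` object.
#' @param ... Unused.
#' @export
autoplot.patch_stats <- function(object, ...) {
  ggplot2::ggplot(object$duration_hist,
                  ggplot2::aes(x = .data$center, y = .data$count)) +
    ggplot2::geom_col(width = 18, fill = "grey35") +
    ggplot2::labs(x = "Patch duration (s, bin centres)",
                  y = "Patches",
                  title = sprintf("%.2f patches/10 um^2/min",
                                  object$frequency_per10um2_min)) +
    ggplot2::theme_minimal()
}

#' Plot a CoV map
#'
#' @param object A `cov_result`.
#' @param ... Unused.
#' @export
autoplot.cov_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$cov)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "CoV") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a calibration curve
#'
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$multiplier, y = .data$statistic)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$statistic - .data$se,
      ymax = .data$statistic + .data$se)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "Frequency multiplier", y = object$statistic) +
    ggplot2::theme_minimal()
}

#' Plot a FRAP fit over its data
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s,
                                       y = .data$normalized)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (s)", y = "Normalized intensity") +
    ggplot2::theme_minimal()
  if (identical(object$flag, "ok")) {
    tt <- seq(min(d$time_s), max(d$time_s), length.out = 200)
    fit <- object$n0 + (object$plateau - object$n0) *
      (1 - exp(-(tt - object$t0_s) / object$tau_s))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(time_s = tt, normalized = fit),
      colour = "red3")
  }
  p
}
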