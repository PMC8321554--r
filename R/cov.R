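#' Per-pixel coefficient-of-variation map
#'
#' The tracking-free dynamics statistic: for every masked pixel, the
#' population standard deviation of its intensity over time divided by
#' its temporal mean. Pixels with non-positive mean get CoV 0 and are
#' flagged invalid. The statistic is invariant to global intensity
#' scaling, so it compares genotypes without any detection threshold.
#'
#' @param movie A [patch_movie()] (>= 2 frames).
#' @param mask A non-empty [patch_mask()].
#' @return A `cov_result`: list with `cov_map` (matrix, NA outside the
#'   mask), `mean_cov` (mean over valid masked pixels), `n_valid`, and
#'   `mask`.
#' @export
cov_map <- function(movie, mask) {
  stopifnot(inherits(movie, "patch_movie"), inherits(mask, "patch_mask"))
  if (!any(mask$pixels)) abort_ap("mask is empty")
  d <- dim(movie$data)
  flat <- matrix(movie$data, nrow = d[1])  # frames x pixels
  sel <- as.vector(mask$pixels)
  mu <- colMeans(flat[, sel, drop = FALSE])
  sigma <- sqrt(pmax(0, colMeans(flat[, sel, drop = FALSE]^2) - mu^2))
  cv <- ifelse(mu > 0, sigma / mu, 0)
  cmap <- matrix(NA_real_, d[2], d[3])
  cmap[mask$pixels] <- cv
  structure(
    list(cov_map = cmap,
         mean_cov = mean(cv[mu > 0]),
         n_valid = sum(mu > 0),
         n_invalid = sum(mu <= 0),
         mask = mask),
    class = "cov_result"
  )
}

#' @export
print.cov_result <- function(x, ...) {
  cat(sprintf("<cov_result> mean CoV %.4f over %d masked pixels\n",
              x$mean_cov, x$n_valid))
  invisible(x)
}

build_histogram <- function(values, n_bins) {
  if (length(values) < 2 || diff(range(values)) == 0) {
    abort_ap("thresholding needs >= 2 distinct values")
  }
  rng <- range(values)
  width <- diff(rng) / n_bins
  idx <- pmin(n_bins, floor((values - rng[1]) / width) + 1L)
  list(counts = tabulate(idx, nbins = n_bins),
       centers = rng[1] + (seq_len(n_bins) - 0.5) * width,
       width = width)
}

#' Li minimum cross-entropy threshold
#'
#' Iterative minimum cross-entropy thresholding on an `n_bins`-bin
#' histogram spanning the data range: starting from the data mean, the
#' threshold is updated as the cross-entropy stationarity point
#' `t <- (mu_below - mu_above) / (log(mu_below) - log(mu_above))` until
#' it moves less than a small tolerance. A few additional quantile
#' starting points guard against convergence to a secondary stationary
#' point; the candidate with the lowest cross-entropy is returned, in
#' data units.
#'
#' @param values Numeric vector (>= 2 distinct values).
#' @param n_bins Histogram bins (default 256).
#' @return The threshold (scalar, data units).
#' @export
threshold_li <- function(values, n_bins = 256L) {
  h <- build_histogram(values, n_bins)
  # cross-entropy needs positive support: shift if necessary
  shift <- if (min(h$centers) <= 0) h$width - min(h$centers) else 0
  g <- h$centers + shift
  w <- h$counts
  tol <- h$width / 100
  iterate <- function(t0) {
    t <- t0
    for (it in 1:200) {
      below <- g <= t
      if (!any(w[below]) || !any(w[!below])) break
      mu_b <- sum(w[below] * g[below]) / sum(w[below])
      mu_a <- sum(w[!below] * g[!below]) / sum(w[!below])
      t_new <- (mu_b - mu_a) / (log(mu_b) - log(mu_a))
      if (!is.finite(t_new)) break
      if (abs(t_new - t) < tol) {
        t <- t_new
        break
      }
      t <- t_new
    }
    t
  }
  crit <- function(t) {
    below <- g <= t
    if (!any(w[below]) || !any(w[!below])) return(Inf)
    mu_b <- sum(w[below] * g[below]) / sum(w[below])
    mu_a <- sum(w[!below] * g[!below]) / sum(w[!below])
    -(sum(w[below] * g[below]) * log(mu_b) +
        sum(w[!below] * g[!below]) * log(mu_a))
  }
  mu0 <- sum(w * g) / sum(w)
  starts <- unique(c(mu0, stats::quantile(values + shift,
                                          c(0.25, 0.5, 0.75),
                                          names = FALSE)))
  cands <- vapply(starts, iterate, numeric(1))
  best <- cands[which.min(vapply(cands, crit, numeric(1)))]
  best - shift
}

#' Moment-preserving (Tsai) threshold
#'
#' Chooses the cut point such that thresholding preserves the first three
#' gray-level moments of the histogram: the preserved below-threshold
#' fraction `p0` follows in closed form from the moments, and the
#' threshold is the histogram percentile at `p0`, returned in data units.
#'
#' @inheritParams threshold_li
#' @return The threshold (scalar, data units).
#' @export
threshold_moments <- function(values, n_bins = 256L) {
  h <- build_histogram(values, n_bins)
  p <- h$counts / sum(h$counts)
  g <- h$centers
  m1 <- sum(p * g); m2 <- sum(p * g^2); m3 <- sum(p * g^3)
  cd <- m2 - m1^2
  if (cd <= 0) abort_ap("degenerate histogram (zero variance)")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) abort_ap("degenerate histogram (complex moment roots)")
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(p)
  k <- which.min(abs(cum - p0))  # gray level nearest the preserved fraction
  g[k] + h$width / 2  # threshold at that bin's upper edge
}

#' Fraction of highly variant pixels
#'
#' Thresholds the masked CoV values with the chosen automatic algorithm
#' and returns the fraction of masked pixels above the threshold. Li and
#' Moments generally differ on skewed data; both are reported by
#' [glance.cov_result()], never silently swapped.
#'
#' @param cov A `cov_result` from [cov_map()].
#' @param method `"li"` or `"moments"`.
#' @param n_bins Histogram bins for the threshold (default 256).
#' @return Fraction in `[0, 1]`.
#' @export
variant_area_fraction <- function(cov, method = c("li", "moments"),
                                  n_bins = 256L) {
  method <- match.arg(method)
  vals <- cov$cov_map[cov$mask$pixels]
  thr <- if (method == "li") threshold_li(vals, n_bins) else
    threshold_moments(vals, n_bins)
  mean(vals > thr)
}
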