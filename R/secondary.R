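#' Masked Pearson colocalization
#'
#' Pearson correlation of two channels over the voxels of a (2-D or 3-D)
#' mask, the standard colocalization coefficient for reconstructed image
#' stacks. Background should be removed upstream (see
#' [rolling_ball_subtract()], applied slice-wise with the standard 50 px
#' radius). R is invariant under independent affine intensity transforms
#' of each channel.
#'
#' @param channel_a,channel_b Numeric arrays of equal shape.
#' @param mask Logical array of the same shape (non-empty).
#' @return Pearson R in `[-1, 1]`.
#' @export
pearson_colocalization <- function(channel_a, channel_b, mask) {
  if (!identical(dim(channel_a), dim(channel_b)) ||
      !identical(dim(channel_a), dim(mask))) {
    abort_ap("channels and mask must share one shape")
  }
  if (!any(mask)) abort_ap("mask is empty")
  a <- channel_a[mask]
  b <- channel_b[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_ap("zero variance within the mask")
  }
  stats::cor(a, b)
}

#' Double-normalize a FRAP trace
#'
#' Standard FRAP double normalization: the background-subtracted bleach
#' ROI is divided by the background-subtracted unbleached reference ROI
#' (cancelling imaging-induced photobleaching), then scaled so the
#' prebleach level is 1:
#' `r(t) = (bleach - bg) / (reference - bg)`;
#' `N(t) = r(t) / mean(r over prebleach frames)`.
#'
#' @param trace Tibble/data frame with columns `time_s, bleach,
#'   reference, background`.
#' @param bleach_frame Index of the first postbleach frame (>= 2, i.e. at
#'   least one prebleach frame).
#' @return The trace tibble with added columns `ratio` and `normalized`.
#' @export
frap_normalize <- function(trace, bleach_frame) {
  need <- c("time_s", "bleach", "reference", "background")
  if (!all(need %in% names(trace))) {
    abort_ap("trace needs columns: %s", paste(need, collapse = ", "))
  }
  if (bleach_frame < 2 || bleach_frame > nrow(trace)) {
    abort_ap("bleach_frame must leave >= 1 prebleach frame")
  }
  ref <- trace$reference - trace$background
  if (any(ref <= 0)) abort_ap("reference - background must be > 0")
  r <- (trace$bleach - trace$background) / ref
  pre <- mean(r[seq_len(bleach_frame - 1L)])
  if (pre <= 0) abort_ap("non-positive prebleach level")
  out <- tibble::as_tibble(trace)
  out$ratio <- r
  out$normalized <- r / pre
  out
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of `N(t) = N0 + (M - N0) * (1 - exp(-(t - t0)/tau))`
#' to the postbleach portion of a double-normalized trace;
#' `mobile_fraction = (M - N0) / (1 - N0)`. A flat postbleach signal or a
#' failed fit is flagged rather than silently returned.
#'
#' @param trace Output of [frap_normalize()].
#' @param bleach_frame Index of the first postbleach frame.
#' @return A `frap_fit` object with `tau_s`, `mobile_fraction`,
#'   `plateau`, `n0`, `residual_rms`, and a `flag` (`"ok"`,
#'   `"unidentifiable"`, or `"fit_failed"`).
#' @export
frap_fit <- function(trace, bleach_frame) {
  if (!"normalized" %in% names(trace)) {
    abort_ap("run frap_normalize() first")
  }
  post <- trace[bleach_frame:nrow(trace), , drop = FALSE]
  if (nrow(post) < 10) abort_ap("need >= 10 postbleach points")
  t0 <- post$time_s[1]
  tt <- post$time_s - t0
  y <- post$normalized
  n0_start <- y[1]
  plateau_start <- mean(utils::tail(y, max(3, nrow(post) %/% 5)))
  res <- function(fit, flag) {
    structure(
      list(tau_s = fit$tau, mobile_fraction = fit$mobile,
           plateau = fit$M, n0 = fit$n0,
           residual_rms = fit$rms, flag = flag,
           t0_s = t0, data = post),
      class = "frap_fit")
  }
  if (stats::sd(y) < 1e-10 || plateau_start <= n0_start + 1e-10) {
    return(res(list(tau = NA_real_, mobile = 0, M = plateau_start,
                    n0 = n0_start, rms = pop_sd(y)),
               "unidentifiable"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ n0 + (M - n0) * (1 - exp(-tt / tau)),
      start = list(n0 = n0_start, M = plateau_start,
                   tau = max(tt[length(tt)] / 3, 1e-3)),
      lower = c(n0 = -Inf, M = -Inf, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(res(list(tau = NA_real_, mobile = NA_real_, M = NA_real_,
                    n0 = n0_start, rms = NA_real_), "fit_failed"))
  }
  cf <- stats::coef(fit)
  flag <- "ok"
  if (cf[["tau"]] <= 2e-6 || cf[["tau"]] >= 100 * max(tt)) {
    flag <- "unidentifiable"  # tau at bound: kinetics not resolved
  }
  mobile <- (cf[["M"]] - cf[["n0"]]) / (1 - cf[["n0"]])
  res(list(tau = cf[["tau"]], mobile = mobile, M = cf[["M"]],
           n0 = cf[["n0"]],
           rms = sqrt(mean(stats::residuals(fit)^2))), flag)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> tau = %.3g s, mobile fraction = %.3g, plateau = %.3g [%s]\n",
    x$tau_s, x$mobile_fraction, x$plateau, x$flag))
  invisible(x)
}
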