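#' Laplacian-of-Gaussian blob kernel
#'
#' Builds a sign-flipped, scale-normalized LoG kernel at scale `sigma_px`
#' and calibrates it so that the response at the centre of a
#' scale-matched Gaussian blob of peak amplitude 1 equals 1. A spot's
#' "quality" is therefore its blob contrast in intensity units, which is
#' what the probe-normalized detection threshold is compared against.
#'
#' @param sigma_px Kernel scale in pixels; the standard blob-radius
#'   relation for a 2-D LoG gives `sigma = diameter / (2 * sqrt(2))`.
#' @return A numeric matrix (odd-sized, zero-sum, calibrated).
#' @export
log_kernel <- function(sigma_px) {
  half <- max(2L, ceiling(4 * sigma_px))
  d <- -half:half
  r2 <- outer(d^2, d^2, `+`)
  g <- exp(-r2 / (2 * sigma_px^2))
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 * g  # -sigma^2 * laplacian(G), unscaled
  k <- k - mean(k)                              # zero response to flat signal
  blob <- exp(-r2 / (2 * sigma_px^2))           # matched unit-peak blob
  k / sum(k * blob)
}

# Quadratic sub-pixel refinement of a maximum from its 3x3 response
# neighbourhood; returns c(dy, dx) clamped to [-1, 1].
quad_subpixel <- function(nb) {
  dxv <- (nb[2, 3] - nb[2, 1]) / 2
  dyv <- (nb[3, 2] - nb[1, 2]) / 2
  dxx <- nb[2, 3] - 2 * nb[2, 2] + nb[2, 1]
  dyy <- nb[3, 2] - 2 * nb[2, 2] + nb[1, 2]
  dxy <- (nb[3, 3] - nb[3, 1] - nb[1, 3] + nb[1, 1]) / 4
  det <- dxx * dyy - dxy^2
  if (!is.finite(det) || det <= 0 || dxx >= 0) return(c(0, 0))
  dx <- -(dyy * dxv - dxy * dyv) / det  # solve H d = -g
  dy <- -(dxx * dyv - dxy * dxv) / det
  c(max(-1, min(1, dy)), max(-1, min(1, dx)))
}

#' Detect sub-pixel spots in one frame
#'
#' Candidates are strict local maxima of the LoG response within the
#' mask, with a minimum separation of one spot radius (greedy suppression
#' by descending response). A candidate is retained if its score exceeds
#' `threshold_factor * probe_mean`, where `probe_mean` is the mean probe
#' intensity in the presynaptic area over the whole movie and the score is
#' the calibrated LoG quality (default) or the raw disc-aggregated peak
#' intensity (`threshold_on = "intensity"`). Positions are refined by 2-D
#' quadratic interpolation of the response in the 3x3 neighbourhood.
#'
#' @param frame_image Numeric matrix `[row, col]`.
#' @param mask A [patch_mask()] (non-empty, same shape).
#' @param pixel_size_um Pixel size in um.
#' @param params Detection parameter list (see [patch_config()]
#'   `$detection`).
#' @param probe_mean Movie-wide mean masked intensity (one global
#'   threshold per movie).
#' @return Tibble with columns `x_um, y_um, peak_intensity, quality`
#'   (`peak_intensity` is the mean raw intensity within one spot radius of
#'   the centre, the aggregation particle trackers report).
#' @export
detect_spots <- function(frame_image, mask, pixel_size_um,
                         params = patch_config()$detection,
                         probe_mean = mean(frame_image[mask$pixels])) {
  if (!any(mask$pixels)) abort_ap("mask is empty")
  if (!all(dim(frame_image) == dim(mask$pixels))) {
    abort_ap("frame and mask dimensions differ")
  }
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (isTRUE(params$median_filter)) {
    frame_image <- EBImage::medianFilter(
      frame_image / max(frame_image, 1), size = 1L) * max(frame_image, 1)
  }
  sigma_px <- params$diameter_um / (2 * sqrt(2)) / pixel_size_um
  kern <- log_kernel(sigma_px)
  resp <- EBImage::filter2(frame_image, kern, boundary = "replicate")
  nr <- nrow(resp); nc <- ncol(resp)
  # strict 8-neighbour local maxima with positive response, inside mask
  is_max <- matrix(FALSE, nr, nc)
  core_r <- 2:(nr - 1); core_c <- 2:(nc - 1)
  m <- resp[core_r, core_c]
  is_max[core_r, core_c] <-
    m > resp[core_r - 1, core_c - 1] & m > resp[core_r - 1, core_c] &
    m > resp[core_r - 1, core_c + 1] & m > resp[core_r, core_c - 1] &
    m > resp[core_r, core_c + 1] & m > resp[core_r + 1, core_c - 1] &
    m > resp[core_r + 1, core_c] & m > resp[core_r + 1, core_c + 1] &
    m > 0
  is_max <- is_max & mask$pixels
  cand <- which(is_max)
  empty <- tibble::tibble(x_um = double(), y_um = double(),
                          peak_intensity = double(), quality = double())
  if (length(cand) == 0) return(empty)
  rows <- (cand - 1L) %% nr + 1L
  cols <- (cand - 1L) %/% nr + 1L
  q <- resp[cand]
  ord <- order(q, decreasing = TRUE)
  rows <- rows[ord]; cols <- cols[ord]; q <- q[ord]
  # minimum separation: one spot radius
  min_sep <- params$diameter_um / 2 / pixel_size_um
  keep <- rep(TRUE, length(q))
  for (i in seq_along(q)) {
    if (!keep[i]) next
    if (i < length(q)) {
      later <- (i + 1):length(q)
      d2 <- (rows[later] - rows[i])^2 + (cols[later] - cols[i])^2
      keep[later[d2 <= min_sep^2]] <- FALSE
    }
  }
  rows <- rows[keep]; cols <- cols[keep]; q <- q[keep]
  # disc-aggregated raw peak intensity
  rad <- max(1, min_sep)
  off <- disc_offsets(rad)
  peak <- vapply(seq_along(q), function(i) {
    rr <- rows[i] + off[, 1]; cc <- cols[i] + off[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    mean(frame_image[cbind(rr[ok], cc[ok])])
  }, numeric(1))
  score <- if (identical(params$threshold_on, "intensity")) peak else q
  sel <- score >= params$threshold_factor * probe_mean
  rows <- rows[sel]; cols <- cols[sel]; q <- q[sel]; peak <- peak[sel]
  if (length(q) == 0) return(empty)
  # sub-pixel localization on the response surface
  dy <- numeric(length(q)); dx <- numeric(length(q))
  if (isTRUE(params$subpixel %||% TRUE)) {
    for (i in seq_along(q)) {
      if (rows[i] > 1 && rows[i] < nr && cols[i] > 1 && cols[i] < nc) {
        o <- quad_subpixel(resp[(rows[i] - 1):(rows[i] + 1),
                                (cols[i] - 1):(cols[i] + 1)])
        dy[i] <- o[1]; dx[i] <- o[2]
      }
    }
  }
  tibble::tibble(
    x_um = (cols + dx - 0.5) * pixel_size_um,
    y_um = (rows + dy - 0.5) * pixel_size_um,
    peak_intensity = peak,
    quality = q
  )
}

#' Detect spots in every frame of a movie
#'
#' Computes the movie-wide probe mean (mean masked intensity over all
#' frames -- the normalization of the published threshold rule) and runs
#' [detect_spots()] per frame.
#'
#' @param movie A [patch_movie()].
#' @param mask A [patch_mask()].
#' @param params Detection parameter list.
#' @return Tibble with columns `frame, x_um, y_um, peak_intensity,
#'   quality`, plus attribute `probe_mean`.
#' @export
detect_movie_spots <- function(movie, mask,
                               params = patch_config()$detection) {
  probe_mean <- mean(matrix(movie$data,
                            nrow = n_frames(movie))[, as.vector(mask$pixels)])
  res <- purrr::map_dfr(seq_len(n_frames(movie)), function(t) {
    sp <- detect_spots(movie$data[t, , ], mask, movie$pixel_size_um,
                       params, probe_mean = probe_mean)
    sp$frame <- t
    sp
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(), x_um = double(),
                          y_um = double(), peak_intensity = double(),
                          quality = double())
  } else {
    res <- res[, c("frame", "x_um", "y_um", "peak_intensity", "quality")]
  }
  attr(res, "probe_mean") <- probe_mean
  res
}
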