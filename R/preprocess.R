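#' Translation registration of a timelapse
#'
#' Aligns every frame to the first by the translation maximizing the
#' (mean-subtracted) cross-correlation, computed via FFT, with the integer
#' peak refined to sub-pixel precision by a 3-point parabolic fit along
#' each axis. Shifts are applied by bilinear interpolation; pixels sampled
#' from outside the field are filled with the frame median. Fixed-specimen
#' imaging justifies a translation-only model.
#'
#' @param movie A [patch_movie()].
#' @param max_shift_px Maximum allowed |shift| per axis; a correlation
#'   peak at the search boundary is clamped with a warning.
#' @return A list with `movie` (registered [patch_movie()]) and `shifts`
#'   (tibble `frame, dy_px, dx_px`; frame 1 is (0, 0)).
#' @export
register_translation <- function(movie, max_shift_px = 5) {
  stopifnot(inherits(movie, "patch_movie"))
  n_t <- n_frames(movie)
  ref <- movie$data[1, , ]
  nr <- nrow(ref); nc <- ncol(ref)
  f_ref <- stats::fft(ref - mean(ref))
  data <- movie$data
  shifts <- matrix(0, n_t, 2)
  clamped <- FALSE
  for (t in 2:n_t) {
    fr <- movie$data[t, , ]
    cc <- Re(stats::fft(Conj(f_ref) * stats::fft(fr - mean(fr)),
                        inverse = TRUE))
    # displacement grid: index 1 is shift 0; wrap negative shifts
    dy_all <- c(0:(nr - 1)); dy_all[dy_all > nr / 2] <- dy_all[dy_all > nr / 2] - nr
    dx_all <- c(0:(nc - 1)); dx_all[dx_all > nc / 2] <- dx_all[dx_all > nc / 2] - nc
    ok <- outer(abs(dy_all) <= max_shift_px, abs(dx_all) <= max_shift_px)
    cc_ok <- cc
    cc_ok[!ok] <- -Inf
    pk <- arrayInd(which.max(cc_ok), dim(cc))
    dy <- dy_all[pk[1]]; dx <- dx_all[pk[2]]
    if (abs(dy) >= max_shift_px || abs(dx) >= max_shift_px) clamped <- TRUE
    # parabolic sub-pixel refinement on the wrapped correlation surface
    gy <- function(d) cc[(pk[1] - 1 + d) %% nr + 1, pk[2]]
    gx <- function(d) cc[pk[1], (pk[2] - 1 + d) %% nc + 1]
    sub_off <- function(m1, m0, p1) {
      den <- m1 - 2 * m0 + p1
      if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
    }
    dy <- dy + sub_off(gy(-1), gy(0), gy(1))
    dx <- dx + sub_off(gx(-1), gx(0), gx(1))
    dy <- max(-max_shift_px, min(max_shift_px, dy))
    dx <- max(-max_shift_px, min(max_shift_px, dx))
    shifts[t, ] <- c(dy, dx)
    data[t, , ] <- shift_bilinear(fr, -dy, -dx, fill = stats::median(fr))
  }
  if (clamped) {
    warning("correlation peak at the search boundary; shift clamped",
            call. = FALSE)
  }
  list(
    movie = patch_movie(pmax(data, 0), movie$pixel_size_um,
                        movie$frame_interval_s),
    shifts = tibble::tibble(frame = seq_len(n_t),
                            dy_px = shifts[, 1], dx_px = shifts[, 2])
  )
}

# Non-flat grayscale erosion/dilation with a spherical-cap structuring
# element. Images are padded by replication so the background estimate
# stays <= the input at borders.
ball_element <- function(radius) {
  off <- disc_offsets(radius)
  h <- sqrt(pmax(0, radius^2 - off[, 1]^2 - off[, 2]^2))
  list(off = off, h = h - max(h))  # peak at 0, negative flanks
}

gray_erode_ball <- function(img, elem) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(elem$off))) {
    sh <- shift_int(img, -elem$off[k, 1], -elem$off[k, 2], fill = Inf)
    # replicate-pad: fill exposed edges with the nearest valid values
    sh[!is.finite(sh)] <- img[!is.finite(sh)]
    out <- pmin(out, sh - elem$h[k])
  }
  out
}

gray_dilate_ball <- function(img, elem) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(elem$off))) {
    sh <- shift_int(img, elem$off[k, 1], elem$off[k, 2], fill = -Inf)
    sh[!is.finite(sh)] <- img[!is.finite(sh)]
    out <- pmax(out, sh + elem$h[k])
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2-D image as the grayscale opening by a
#' ball-shaped (spherical-cap) structuring element of the given radius --
#' the surface traced by a ball rolled under the intensity landscape --
#' and subtracts it, flooring at zero. Defining properties: the output is
#' everywhere `>= 0` and `<= input`, a constant image maps to zero, and
#' features much smaller than the radius are preserved. For radii above
#' 16 px the estimate is computed on a block-min-shrunken image and
#' re-enlarged (the classical speedup), then capped at the input.
#'
#' @param image Numeric matrix.
#' @param radius_px Ball radius in pixels (> 0), default 50.
#' @return Background-subtracted matrix of the same shape.
#' @export
rolling_ball_subtract <- function(image, radius_px = 50) {
  if (!is.matrix(image)) abort_ap("`image` must be a matrix")
  if (radius_px <= 0) abort_ap("radius_px must be > 0")
  shrink <- if (radius_px > 16) ceiling(radius_px / 16) else 1L
  if (shrink > 1L) {
    nr <- nrow(image); nc <- ncol(image)
    nr2 <- ceiling(nr / shrink); nc2 <- ceiling(nc / shrink)
    small <- matrix(Inf, nr2, nc2)
    for (i in seq_len(nr2)) {
      rs <- ((i - 1) * shrink + 1):min(nr, i * shrink)
      for (j in seq_len(nc2)) {
        cs <- ((j - 1) * shrink + 1):min(nc, j * shrink)
        small[i, j] <- min(image[rs, cs])
      }
    }
    elem <- ball_element(radius_px / shrink)
    bg_small <- gray_dilate_ball(gray_erode_ball(small, elem), elem)
    # bilinear re-enlargement to the original grid
    yi <- pmin((seq_len(nr) - 0.5) / shrink + 0.5, nr2)
    xi <- pmin((seq_len(nc) - 0.5) / shrink + 0.5, nc2)
    y0 <- pmax(1L, pmin(nr2 - 1L, floor(yi))); fy <- pmin(pmax(yi - y0, 0), 1)
    x0 <- pmax(1L, pmin(nc2 - 1L, floor(xi))); fx <- pmin(pmax(xi - x0, 0), 1)
    bg <- bg_small[y0, x0] * outer(1 - fy, 1 - fx) +
      bg_small[y0 + 1L, x0] * outer(fy, 1 - fx) +
      bg_small[y0, x0 + 1L] * outer(1 - fy, fx) +
      bg_small[y0 + 1L, x0 + 1L] * outer(fy, fx)
  } else {
    elem <- ball_element(radius_px)
    bg <- gray_dilate_ball(gray_erode_ball(image, elem), elem)
  }
  bg <- pmin(bg, image)
  out <- image - bg
  out[out < 0] <- 0
  out
}

#' Generate the presynaptic mask from a movie
#'
#' The mask is computed once from the Gaussian-blurred maximum-over-time
#' projection (patch events must not move the mask: frequency
#' normalization needs one stable area), thresholded by the chosen
#' algorithm.
#'
#' @param movie A [patch_movie()].
#' @param blur_sigma_px Gaussian blur sigma in pixels (default 2; tune per
#'   experiment).
#' @param method One of `"otsu"`, `"li"`, `"moments"`, or `"fixed:<value>"`
#'   for an absolute intensity threshold.
#' @param keep_largest Retain only the largest connected component?
#' @return A [patch_mask()].
#' @export
make_presynaptic_mask <- function(movie, blur_sigma_px = 2,
                                  method = "otsu", keep_largest = FALSE) {
  stopifnot(inherits(movie, "patch_movie"))
  proj <- apply(movie$data, c(2, 3), max)
  img <- if (blur_sigma_px > 0) EBImage::gblur(proj, blur_sigma_px) else proj
  rng <- range(img)
  if (startsWith(method, "fixed:")) {
    thr <- as.numeric(sub("^fixed:", "", method))
    if (is.na(thr)) abort_ap("invalid fixed threshold in '%s'", method)
    px <- img >= thr
  } else if (method == "otsu") {
    if (rng[2] <= rng[1]) abort_ap("empty mask: image is constant")
    thr <- EBImage::otsu(img, range = rng, levels = 256L)
    px <- img > thr
  } else if (method == "li") {
    px <- img > threshold_li(as.vector(img))
  } else if (method == "moments") {
    px <- img > threshold_moments(as.vector(img))
  } else {
    abort_ap("unknown mask method '%s'", method)
  }
  if (!any(px)) abort_ap("empty mask after thresholding")
  if (keep_largest) {
    lab <- EBImage::bwlabel(px * 1)
    tab <- tabulate(lab[lab > 0])
    px <- lab == which.max(tab)
  }
  patch_mask(matrix(as.logical(px), nrow(px), ncol(px)),
             movie$pixel_size_um)
}
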