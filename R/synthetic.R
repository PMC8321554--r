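#' Specification of a synthetic presynaptic timelapse
#'
#' Describes everything needed to generate a simulated movie with known
#' ground truth: the bouton-chain geometry, the imaging regime, the
#' transient-event statistics, and the noise model. The defaults emulate
#' the in-vivo study conditions: a chain of ~10 um^2 boutons expressing a
#' diffuse F-actin probe, transient ~0.6 um bright patches occurring at a
#' rate of a few events per 10 um^2 per minute with lognormal durations
#' (mean 48 s, sd 45.6 s) and relative amplitude ~68%, imaged at 0.25 Hz
#' for 89 frames with shot and read noise.
#'
#' @param n_boutons Number of boutons in the chain.
#' @param bouton_radius_um Bouton radius in um (default 2, ~12.6 um^2 per
#'   bouton, on the order of a synaptic bouton).
#' @param pixel_size_um,frame_interval_s,n_frames Imaging regime.
#' @param baseline Diffuse probe intensity B inside the mask (detector
#'   units).
#' @param noise_sigma Gaussian read-noise sd (detector units).
#' @param shot_noise Apply Poisson shot noise?
#' @param bleach_rate Photobleaching rate k (per second); 0 disables.
#' @param event_frequency Event rate f in events / 10 um^2 / min.
#' @param duration_mean_s,duration_sd_s Lognormal event duration moments.
#' @param amplitude_ratio Event peak added as `amplitude_ratio * baseline`.
#' @param spot_sigma_um Spatial sd of the event Gaussian
#'   (default 0.255 um, i.e. 0.6 um FWHM / 2.355).
#' @param edge_blur_um Gaussian blur applied to the baseline mask step,
#'   emulating the microscope PSF at the bouton boundary. Defaults to
#'   `spot_sigma_um` (one optical train blurs baseline and patches
#'   alike); 0 gives an ideal hard-edged baseline.
#' @param margin_um Dark margin around the bouton chain.
#' @param pixel_mode If `TRUE`, generate the per-pixel flicker model used
#'   for CoV validation instead of spatial events.
#' @param dynamic_pixel_fraction Fraction p of mask pixels that flicker in
#'   pixel mode.
#' @param pixel_rate_per_min Per-pixel flicker event rate (events/min) in
#'   pixel mode.
#' @param rng_seed Integer seed; every stochastic step derives its
#'   randomness from it.
#' @return A `synthetic_spec` (named list).
#' @export
synthetic_spec <- function(n_boutons = 3L, bouton_radius_um = 2,
                           pixel_size_um = 0.13, frame_interval_s = 4,
                           n_frames = 89L, baseline = 100,
                           noise_sigma = 10, shot_noise = TRUE,
                           bleach_rate = 0, event_frequency = 6,
                           duration_mean_s = 48, duration_sd_s = 45.6,
                           amplitude_ratio = 0.68, spot_sigma_um = 0.255,
                           edge_blur_um = NULL, margin_um = 1,
                           pixel_mode = FALSE, dynamic_pixel_fraction = 0,
                           pixel_rate_per_min = 1, rng_seed = 1L) {
  spec <- list(
    n_boutons = as.integer(n_boutons), bouton_radius_um = bouton_radius_um,
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames), baseline = baseline,
    noise_sigma = noise_sigma, shot_noise = isTRUE(shot_noise),
    bleach_rate = bleach_rate, event_frequency = event_frequency,
    duration_mean_s = duration_mean_s, duration_sd_s = duration_sd_s,
    amplitude_ratio = amplitude_ratio, spot_sigma_um = spot_sigma_um,
    edge_blur_um = edge_blur_um %||% spot_sigma_um, margin_um = margin_um,
    pixel_mode = isTRUE(pixel_mode),
    dynamic_pixel_fraction = dynamic_pixel_fraction,
    pixel_rate_per_min = pixel_rate_per_min,
    rng_seed = as.integer(rng_seed)
  )
  assert_scalar_num(spec$event_frequency, "event_frequency", nonneg = TRUE)
  assert_scalar_num(spec$amplitude_ratio, "amplitude_ratio", positive = TRUE)
  assert_scalar_num(spec$noise_sigma, "noise_sigma", nonneg = TRUE)
  if (spec$dynamic_pixel_fraction < 0 || spec$dynamic_pixel_fraction > 1) {
    abort_ap("dynamic_pixel_fraction must lie in [0, 1]")
  }
  if (spec$duration_mean_s < spec$frame_interval_s) {
    abort_ap("duration_mean_s must be >= frame_interval_s")
  }
  structure(spec, class = "synthetic_spec")
}

#' Build the bouton-chain mask for a synthetic spec
#'
#' The geometry is a horizontal chain of touching discs; the mask is the
#' union of the discs evaluated at pixel centres, surrounded by a dark
#' margin.
#'
#' @param spec A [synthetic_spec()].
#' @return A [patch_mask()].
#' @export
make_geometry <- function(spec) {
  if (spec$n_boutons < 1L) abort_ap("geometry needs >= 1 bouton")
  r <- spec$bouton_radius_um
  m <- spec$margin_um
  psz <- spec$pixel_size_um
  centers_x <- m + r + (seq_len(spec$n_boutons) - 1) * 2 * r
  center_y <- m + r
  width_um <- 2 * m + spec$n_boutons * 2 * r
  height_um <- 2 * m + 2 * r
  nc <- ceiling(width_um / psz)
  nr <- ceiling(height_um / psz)
  xs <- (seq_len(nc) - 0.5) * psz
  ys <- (seq_len(nr) - 0.5) * psz
  px <- matrix(FALSE, nr, nc)
  for (cx in centers_x) {
    px <- px | (outer((ys - center_y)^2, (xs - cx)^2, `+`) <= r^2)
  }
  if (any(px[1, ]) || any(px[nr, ]) || any(px[, 1]) || any(px[, nc])) {
    abort_ap("boutons extend outside the field of view")
  }
  patch_mask(px, psz)
}

#' Draw ground-truth events for a synthetic movie
#'
#' Event count is Poisson with mean
#' `f * (area_um2 / 10) * (n_frames * frame_interval_s / 60)`; positions
#' are uniform over the mask, start frames uniform over the movie, and
#' durations lognormal (moment-matched to `duration_mean_s` /
#' `duration_sd_s`), rounded to at least one frame and clipped at the end
#' of the movie.
#'
#' @param spec A [synthetic_spec()].
#' @param mask A [patch_mask()] from [make_geometry()].
#' @param seed Integer seed (defaults to the spec's).
#' @return Tibble with columns `event_id, x_um, y_um, start_frame,
#'   n_frames, duration_s, amplitude`.
#' @export
sample_events <- function(spec, mask, seed = spec$rng_seed) {
  lambda <- spec$event_frequency * (mask$area_um2 / 10) *
    (spec$n_frames * spec$frame_interval_s / 60)
  with_seed(seed, {
    n <- stats::rpois(1, lambda)
    if (n == 0) {
      return(tibble::tibble(event_id = integer(), x_um = double(),
                            y_um = double(), start_frame = integer(),
                            n_frames = integer(), duration_s = double(),
                            amplitude = double()))
    }
    idx <- which(mask$pixels)
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    nr <- nrow(mask$pixels)
    row <- (pick - 1L) %% nr + 1L
    col <- (pick - 1L) %/% nr + 1L
    psz <- mask$pixel_size_um
    x_um <- (col - 0.5) * psz + stats::runif(n, -0.5, 0.5) * psz
    y_um <- (row - 0.5) * psz + stats::runif(n, -0.5, 0.5) * psz
    start <- sample.int(spec$n_frames, n, replace = TRUE)
    sdlog <- sqrt(log(1 + (spec$duration_sd_s / spec$duration_mean_s)^2))
    meanlog <- log(spec$duration_mean_s) - sdlog^2 / 2
    dur <- stats::rlnorm(n, meanlog, sdlog)
    nf <- pmax(1L, as.integer(round(dur / spec$frame_interval_s)))
    nf <- pmin(nf, spec$n_frames - start + 1L)
    tibble::tibble(event_id = seq_len(n), x_um = x_um, y_um = y_um,
                   start_frame = start, n_frames = nf,
                   duration_s = dur,
                   amplitude = spec$amplitude_ratio * spec$baseline)
  })
}

baseline_image <- function(spec, mask) {
  img <- spec$baseline * (mask$pixels * 1)
  blur_px <- spec$edge_blur_um / spec$pixel_size_um
  if (blur_px > 0) {
    img <- EBImage::gblur(img, sigma = blur_px)
    img[img < 0] <- 0
  }
  img
}

#' Render a noiseless movie from ground-truth events
#'
#' Each frame is the diffuse baseline (B inside the mask, 0 outside, with
#' the mask step smoothed at PSF scale); each active event adds an
#' isotropic 2-D Gaussian of peak `amplitude` and sd `spot_sigma_um` with
#' a rectangular temporal profile. Overlapping events superpose
#' additively.
#'
#' @param events Tibble from [sample_events()].
#' @param mask A [patch_mask()].
#' @param spec A [synthetic_spec()].
#' @return A noiseless [patch_movie()].
#' @export
render_movie <- function(events, mask, spec) {
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  psz <- spec$pixel_size_um
  base <- baseline_image(spec, mask)
  data <- array(rep(base, each = spec$n_frames),
                c(spec$n_frames, nr, nc))
  if (nrow(events) > 0) {
    sig_px <- spec$spot_sigma_um / psz
    half <- ceiling(4 * sig_px)
    for (i in seq_len(nrow(events))) {
      cx <- events$x_um[i] / psz + 0.5  # pixel-centre coordinates
      cy <- events$y_um[i] / psz + 0.5
      rows <- max(1, floor(cy - half)):min(nr, ceiling(cy + half))
      cols <- max(1, floor(cx - half)):min(nc, ceiling(cx + half))
      g <- events$amplitude[i] *
        outer(exp(-(rows - cy)^2 / (2 * sig_px^2)),
              exp(-(cols - cx)^2 / (2 * sig_px^2)))
      frames <- events$start_frame[i]:
        (events$start_frame[i] + events$n_frames[i] - 1L)
      for (t in frames) {
        data[t, rows, cols] <- data[t, rows, cols] + g
      }
    }
  }
  patch_movie(data, psz, spec$frame_interval_s)
}

#' Render the per-pixel flicker model (pixel mode)
#'
#' A seeded random fraction `p` of mask pixels is designated dynamic; each
#' dynamic pixel flickers independently with square-wave events (Poisson
#' starts at `pixel_rate_per_min`, fixed duration `duration_mean_s`,
#' added amplitude `amplitude_ratio * baseline`). Static pixels stay at
#' the baseline. This is the generative model used to validate the
#' coefficient-of-variation statistic.
#'
#' @param spec A [synthetic_spec()] with `pixel_mode = TRUE`.
#' @param seed Integer seed (defaults to the spec's).
#' @return A noiseless [patch_movie()] plus ground truth, as a list
#'   `list(movie, mask, dynamic)` where `dynamic` is the logical matrix of
#'   flickering pixels.
#' @export
pixel_mode_movie <- function(spec, seed = spec$rng_seed) {
  if (!spec$pixel_mode) abort_ap("spec must have pixel_mode = TRUE")
  mask <- make_geometry(spec)
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  n_t <- spec$n_frames
  base <- baseline_image(spec, mask)
  data <- array(rep(base, each = n_t), c(n_t, nr, nc))
  dyn <- matrix(FALSE, nr, nc)
  with_seed(seed, {
    idx <- which(mask$pixels)
    n_dyn <- round(spec$dynamic_pixel_fraction * length(idx))
    if (n_dyn > 0) {
      chosen <- sample(idx, n_dyn)
      dyn[chosen] <- TRUE
      rate_per_frame <- spec$pixel_rate_per_min * spec$frame_interval_s / 60
      dur_frames <- max(1L, as.integer(round(
        spec$duration_mean_s / spec$frame_interval_s)))
      amp <- spec$amplitude_ratio * spec$baseline
      nr_ <- nr
      for (p in chosen) {
        row <- (p - 1L) %% nr_ + 1L
        col <- (p - 1L) %/% nr_ + 1L
        n_ev <- stats::rpois(1, rate_per_frame * n_t)
        if (n_ev == 0) next
        starts <- sample.int(n_t, n_ev, replace = TRUE)
        on <- rep(FALSE, n_t)
        for (s in starts) on[s:min(n_t, s + dur_frames - 1L)] <- TRUE
        data[on, row, col] <- data[on, row, col] + amp
      }
    }
  })
  list(movie = patch_movie(data, spec$pixel_size_um, spec$frame_interval_s),
       mask = mask, dynamic = dyn)
}

#' Apply photobleaching, shot noise and read noise to a noiseless movie
#'
#' `I'(t) = Shot(I(t) * exp(-k * (t - 1) * dt)) + N(0, noise_sigma)`,
#' clipped at zero, with `Shot` a Poisson draw when `shot_noise` is on.
#'
#' @param movie Noiseless [patch_movie()].
#' @param spec A [synthetic_spec()] (supplies `bleach_rate`,
#'   `shot_noise`, `noise_sigma`).
#' @param seed Integer seed (defaults to the spec's).
#' @return A noisy [patch_movie()].
#' @export
apply_noise_and_bleach <- function(movie, spec, seed = spec$rng_seed) {
  if (spec$noise_sigma < 0) abort_ap("noise_sigma must be >= 0")
  data <- movie$data
  n_t <- dim(data)[1]
  if (spec$bleach_rate > 0) {
    decay <- exp(-spec$bleach_rate * (seq_len(n_t) - 1) *
                   movie$frame_interval_s)
    data <- data * decay  # recycles along the frame (first) dimension
  }
  with_seed(seed, {
    if (spec$shot_noise) {
      data[] <- stats::rpois(length(data), data)
    }
    if (spec$noise_sigma > 0) {
      data <- data + stats::rnorm(length(data), 0, spec$noise_sigma)
    }
  })
  data[data < 0] <- 0
  patch_movie(data, movie$pixel_size_um, movie$frame_interval_s)
}

#' Simulate a full synthetic movie with ground truth
#'
#' Convenience wrapper: geometry, event sampling, rendering, and noise,
#' each seeded deterministically from `spec$rng_seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list `list(movie, mask, truth, spec)` where `truth` is the
#'   ground-truth event tibble.
#' @export
simulate_movie <- function(spec) {
  mask <- make_geometry(spec)
  truth <- sample_events(spec, mask, seed = derive_seed(spec$rng_seed, 1L))
  clean <- render_movie(truth, mask, spec)
  noisy <- apply_noise_and_bleach(clean, spec,
                                  seed = derive_seed(spec$rng_seed, 2L))
  list(movie = noisy, mask = mask, truth = truth, spec = spec)
}
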