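#' Calibrated timelapse movie
#'
#' A `patch_movie` holds an intensity stack indexed `[frame, row, col]`
#' together with the spatial and temporal calibration used by every
#' downstream computation. Intensities are promoted to double precision at
#' construction; calibration always comes from the caller (or the run
#' config), never from file metadata.
#'
#' @param data Numeric 3-D array `[frame, row, col]`; all values must be
#'   finite and non-negative, with at least two frames.
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s Seconds between consecutive frames (> 0).
#' @return A `patch_movie` object.
#' @examples
#' mv <- patch_movie(array(1, c(3, 8, 8)), pixel_size_um = 0.13,
#'                   frame_interval_s = 4)
#' n_frames(mv)
#' @export
patch_movie <- function(data, pixel_size_um, frame_interval_s) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_ap("`data` must be a 3-D array [frame, row, col]")
  }
  if (dim(data)[1] < 2L) abort_ap("movie must have >= 2 frames")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) {
    abort_ap("movie intensities must be finite (no NA/NaN/Inf)")
  }
  if (any(data < 0)) abort_ap("movie intensities must be >= 0")
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  assert_scalar_num(frame_interval_s, "frame_interval_s", positive = TRUE)
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s),
    class = "patch_movie"
  )
}

#' @export
print.patch_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<patch_movie> %d frames of %d x %d px (%.3g um/px, %.3g s/frame, %.3g s total)\n",
    d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s,
    d[1] * x$frame_interval_s))
  invisible(x)
}

#' @rdname patch_movie
#' @param x An object.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.patch_movie <- function(x) dim(x$data)[1]

#' Extract one frame of a movie as a matrix
#'
#' @param movie A [patch_movie()].
#' @param frame Frame index (1-based).
#' @return A numeric matrix `[row, col]`.
#' @export
movie_frame <- function(movie, frame) {
  stopifnot(inherits(movie, "patch_movie"))
  movie$data[frame, , ]
}

#' Presynaptic mask
#'
#' A boolean pixel mask with its physical area, used both to restrict
#' detection to the presynaptic region and to normalize patch frequencies
#' (events per 10 um^2 per minute).
#'
#' @param pixels Logical matrix `[row, col]`.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return A `patch_mask` with derived `area_um2`.
#' @export
patch_mask <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    abort_ap("`pixels` must be a logical matrix")
  }
  assert_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!any(pixels)) abort_ap("mask is empty")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         area_um2 = sum(pixels) * pixel_size_um^2),
    class = "patch_mask"
  )
}

#' @export
print.patch_mask <- function(x, ...) {
  cat(sprintf("<patch_mask> %d px, %.2f um^2 (%.3g um/px)\n",
              sum(x$pixels), x$area_um2, x$pixel_size_um))
  invisible(x)
}

#' Read a multi-page TIFF timelapse as a movie
#'
#' Pages must share one shape. If the file interleaves `n_z` Z-slices per
#' time point (pages ordered Z-fastest), each time point is reduced by a
#' maximum intensity projection over its slices before analysis; Z is never
#' tracked.
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param pixel_size_um,frame_interval_s Calibration (supplied by the
#'   caller; TIFF tags are not trusted).
#' @param n_z Number of Z-slices per time point (default 1, i.e. a plain
#'   T x Y x X stack).
#' @return A [patch_movie()].
#' @export
read_movie <- function(path, pixel_size_um, frame_interval_s, n_z = 1L) {
  if (!file.exists(path)) abort_ap("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop degenerate channel dim
    p
  })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    abort_ap("TIFF pages have mixed shapes")
  }
  n_z <- as.integer(n_z)
  if (n_z < 1L) abort_ap("`n_z` must be >= 1")
  if (length(pages) %% n_z != 0L) {
    abort_ap("page count (%d) is not a multiple of n_z (%d)",
             length(pages), n_z)
  }
  n_t <- length(pages) %/% n_z
  if (n_t < 2L) abort_ap("movie must have >= 2 frames (got %d)", n_t)
  data <- array(0, c(n_t, shp[1], shp[2]))
  for (t in seq_len(n_t)) {
    fr <- pages[[(t - 1L) * n_z + 1L]]
    if (n_z > 1L) {
      for (z in 2:n_z) fr <- pmax(fr, pages[[(t - 1L) * n_z + z]])
    }
    data[t, , ] <- fr
  }
  patch_movie(data, pixel_size_um, frame_interval_s)
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Intensities are rounded to integers and stored as 16-bit grayscale
#' (the format microscopes produce); values above 65535 are clipped with
#' a warning. Reading the file back with [read_movie()] reproduces the
#' rounded values exactly.
#'
#' @param movie A [patch_movie()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "patch_movie"))
  mx <- 65535
  if (any(movie$data > mx)) {
    warning("intensities above 65535 clipped on write", call. = FALSE)
  }
  pages <- lapply(seq_len(n_frames(movie)), function(t) {
    pmin(round(movie$data[t, , ]), mx) / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Write spot and track tables to CSV
#'
#' Writes one row per spot (`track_id, frame, x_um, y_um, peak_intensity,
#' quality`) plus a per-track summary table (`track_id, n_spots,
#' duration_s, rel_amplitude, censored_start, censored_end`). Values
#' round-trip through [read_tracks()] unchanged to at least 6 decimals.
#'
#' @param tracks Spot-level tibble as returned by [link_tracks()].
#' @param path Path for the spot-level CSV; the summary table is written
#'   next to it with suffix `_summary.csv`.
#' @param frame_interval_s Frame interval used for summary durations.
#' @param n_movie_frames Total frames in the movie (for censoring flags).
#' @param rel_amplitudes Optional named vector of per-track relative
#'   amplitudes to include in the summary (NA when absent).
#' @return Invisibly, a list with the two paths written.
#' @export
write_tracks <- function(tracks, path, frame_interval_s = NA_real_,
                         n_movie_frames = NA_integer_,
                         rel_amplitudes = NULL) {
  cols <- c("track_id", "frame", "x_um", "y_um", "peak_intensity", "quality")
  spot_tbl <- if (nrow(tracks) == 0) {
    tibble::tibble(track_id = integer(), frame = integer(), x_um = double(),
                   y_um = double(), peak_intensity = double(),
                   quality = double())
  } else {
    tracks[, cols]
  }
  readr::write_csv(spot_tbl, path)
  summary_path <- sub("(\\.csv)?$", "_summary.csv", path)
  smry <- track_summary(tracks, frame_interval_s = frame_interval_s,
                        n_movie_frames = n_movie_frames)
  if (!is.null(rel_amplitudes) && nrow(smry) > 0) {
    smry$rel_amplitude <- unname(rel_amplitudes[as.character(smry$track_id)])
  } else if (!"rel_amplitude" %in% names(smry)) {
    smry$rel_amplitude <- rep(NA_real_, nrow(smry))
  }
  readr::write_csv(smry, summary_path)
  invisible(list(spots = path, summary = summary_path))
}

#' Read a spot-level track CSV written by [write_tracks()]
#'
#' @param path Path to the spot-level CSV.
#' @return A tibble with one row per spot.
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    track_id = readr::col_integer(),
                    frame = readr::col_integer(),
                    .default = readr::col_double()))
}
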