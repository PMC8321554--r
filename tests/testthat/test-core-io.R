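test_that("patch_movie enforces its invariants", {
  expect_s3_class(patch_movie(array(1, c(2, 4, 4)), 0.13, 4), "patch_movie")
  expect_error(patch_movie(array(1, c(1, 4, 4)), 0.13, 4), ">= 2 frames")
  bad <- array(1, c(3, 4, 4)); bad[2, 1, 1] <- NA
  expect_error(patch_movie(bad, 0.13, 4), "finite")
  neg <- array(1, c(3, 4, 4)); neg[1, 1, 1] <- -2
  expect_error(patch_movie(neg, 0.13, 4), ">= 0")
  expect_error(patch_movie(array(1, c(3, 4, 4)), -0.1, 4), "> 0")
  expect_error(patch_movie(array(1, c(3, 4, 4)), 0.13, 0), "> 0")
})

test_that("read_movie ingests plain and Z-interleaved TIFF stacks", {
  # 10-page 64x64 integer stack: identity ingest, intensity-sum conserved
  set.seed(31)
  pages <- lapply(1:10, function(i) {
    matrix(sample(0:4095, 64 * 64, replace = TRUE), 64, 64)
  })
  tmp <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(pages, function(p) p / 65535), tmp,
                  bits.per.sample = 16L, reduce = FALSE)
  mv <- read_movie(tmp, pixel_size_um = 0.13, frame_interval_s = 4)
  expect_equal(n_frames(mv), 10L)
  expect_equal(mv$data[3, , ], pages[[3]], ignore_attr = TRUE)
  expect_equal(sum(mv$data), sum(unlist(pages)))

  # (10, 5, 64, 64) Z-interleaved: per-frame maximum projection over Z
  pages_z <- lapply(1:50, function(i) {
    matrix(sample(0:4095, 64 * 64, replace = TRUE), 64, 64)
  })
  tmpz <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(pages_z, function(p) p / 65535), tmpz,
                  bits.per.sample = 16L, reduce = FALSE)
  mvz <- read_movie(tmpz, 0.13, 4, n_z = 5)
  expect_equal(n_frames(mvz), 10L)
  want <- Reduce(pmax, pages_z[6:10])
  expect_equal(mvz$data[2, , ], want, ignore_attr = TRUE)

  # single page: too few frames
  tmp1 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages[[1]] / 65535, tmp1, bits.per.sample = 16L)
  expect_error(read_movie(tmp1, 0.13, 4), ">= 2 frames")
})

test_that("write_movie/read_movie round-trips integer intensities", {
  sim <- simulate_movie(tiny_spec(rng_seed = 5))
  tmp <- tempfile(fileext = ".tif")
  write_movie(sim$movie, tmp)
  back <- read_movie(tmp, sim$movie$pixel_size_um,
                     sim$movie$frame_interval_s)
  expect_equal(back$data, round(sim$movie$data), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("track tables round-trip through CSV and handle empty input", {
  run <- run_patch_pipeline(tiny_spec(rng_seed = 8))
  tmp <- tempfile(fileext = ".csv")
  paths <- write_tracks(run$filtered$accepted, tmp, frame_interval_s = 4,
                        n_movie_frames = 60)
  back <- read_tracks(tmp)
  expect_equal(nrow(back), nrow(run$filtered$accepted))
  for (col in c("x_um", "y_um", "peak_intensity", "quality")) {
    expect_equal(back[[col]], run$filtered$accepted[[col]],
                 tolerance = 1e-7)
  }
  smry <- readr::read_csv(paths$summary, show_col_types = FALSE)
  expect_equal(nrow(smry), length(unique(run$filtered$accepted$track_id)))
  # byte-identical CSVs on re-run with the same config + input
  tmp2 <- tempfile(fileext = ".csv")
  run2 <- run_patch_pipeline(tiny_spec(rng_seed = 8))
  write_tracks(run2$filtered$accepted, tmp2, frame_interval_s = 4,
               n_movie_frames = 60)
  expect_identical(readLines(tmp), readLines(tmp2))

  empty <- run$filtered$accepted[0, ]
  tmp3 <- tempfile(fileext = ".csv")
  write_tracks(empty, tmp3)
  expect_equal(nrow(read_tracks(tmp3)), 0L)
})

test_that("config defaults mirror the published parameterization", {
  cfg <- patch_config()
  expect_equal(cfg$detection$diameter_um, 0.6)
  expect_equal(cfg$detection$threshold_factor, 0.32)
  expect_false(cfg$detection$median_filter)
  expect_true(cfg$detection$subpixel)
  expect_equal(cfg$tracking$linking_max_um, 0.5)
  expect_equal(cfg$tracking$gap_frames, 0L)
  expect_equal(cfg$tracking$min_spots, 4L)
  expect_equal(cfg$preprocess$rolling_ball_radius_px, 50)
  expect_equal(cfg$cov$n_bins, 256L)
})

test_that("load_config applies defaults, overrides, warnings and errors", {
  f <- tempfile(fileext = ".yml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(cfg$detection$diameter_um, 0.6)

  writeLines("rng_seed: 7", f)
  expect_equal(load_config(f)$rng_seed, 7)

  writeLines("pixel_size_um: -0.2", f)
  expect_error(load_config(f), "> 0")

  writeLines("no_such_key: 1", f)
  expect_warning(load_config(f), "unknown config key")
})
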