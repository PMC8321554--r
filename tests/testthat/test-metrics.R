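test_that("durations use the spot-count convention", {
  expect_equal(track_duration(4, 4), 16)    # 0.25 Hz floor
  expect_equal(track_duration(89, 4), 356)  # 0.25 Hz ceiling
  expect_equal(track_duration(1, 1), 1)
})

test_that("relative amplitude reproduces its arithmetic definition", {
  tr <- tibble::tibble(frame = 1:3, x_um = 1, y_um = 1,
                       peak_intensity = c(10, 30, 20), quality = 1)
  expect_equal(relative_amplitude(tr, mode = "spots"), 1.0)
  trc <- tibble::tibble(frame = 1:3, x_um = 1, y_um = 1,
                        peak_intensity = c(20, 20, 20), quality = 1)
  expect_equal(relative_amplitude(trc, mode = "spots"), 0)
  expect_error(relative_amplitude(tr[1, ], mode = "spots"), ">= 2")
})

test_that("patch frequency is the area-and-time normalized count", {
  expect_equal(patch_frequency(6, 20, 3), 1.0)
  expect_equal(patch_frequency(0, 20, 3), 0)
  expect_equal(patch_frequency(6, 40, 3), patch_frequency(6, 20, 3) / 2)
  expect_error(patch_frequency(6, 0, 3), "> 0")
})

test_that("duration histogram uses 20-s half-open bins at bin centres", {
  h <- duration_histogram(c(16, 16, 48))
  expect_equal(h$center, c(10, 30, 50))
  expect_equal(h$count, c(2, 0, 1))
  h0 <- duration_histogram(numeric(0))
  expect_true(all(h0$count == 0))
  # a value exactly on an edge falls into the upper bin
  h20 <- duration_histogram(20)
  expect_equal(h20$count[h20$bin_lo == 20], 1)
  expect_equal(h20$count[h20$bin_lo == 0], 0)
  expect_error(duration_histogram(5, bin_width_s = 0), "> 0")
})

test_that("range merging follows the two-regime arithmetic", {
  est <- merge_range_frequencies(shared_low = 1.0, shared_high = 1.2,
                                 high_rate_only = 0.2, low_rate_only = 2.0)
  expect_equal(est$merged_frequency, 1.1 + 0.2 + 2.0)
  expect_equal(est$lower_bound, est$upper_bound)

  # adding rejects can only raise the upper bound
  est2 <- merge_range_frequencies(1.0, 1.2, 0.2, 2.0,
                                  rej_shared_low = 0.3, rej_high_only = 0.1)
  expect_equal(est2$merged_frequency, est$merged_frequency)
  expect_gt(est2$upper_bound, est$upper_bound)
  expect_true(est2$lower_bound <= est2$upper_bound)
})

test_that("paired two-rate acquisitions recover the generating frequency", {
  run_regime <- function(spec) {
    sim <- simulate_movie(spec)
    spots <- detect_movie_spots(sim$movie, sim$mask)
    filt <- filter_tracks(link_tracks(spots),
                          frame_interval_s = spec$frame_interval_s,
                          n_movie_frames = spec$n_frames)
    list(stats = patch_stats(filt, sim$movie, sim$mask), filt = filt)
  }
  est <- vapply(1:8, function(s) {
    low <- run_regime(synthetic_spec(rng_seed = 4000 + s))
    high <- run_regime(synthetic_spec(frame_interval_s = 1, n_frames = 139,
                                      rng_seed = 5000 + s))
    m <- merged_frequency_estimate(low$stats, high$stats,
                                   low$filt, high$filt)
    expect_true(m$lower_bound <= m$upper_bound)
    m$merged_frequency
  }, numeric(1))
  expect_lt(abs(mean(est) / 6 - 1), 0.25)
})

test_that("per-movie statistics summarize accepted tracks", {
  sim <- simulate_movie(synthetic_spec(rng_seed = 11))
  spots <- detect_movie_spots(sim$movie, sim$mask)
  filt <- filter_tracks(link_tracks(spots), frame_interval_s = 4,
                        n_movie_frames = 89)
  st <- patch_stats(filt, sim$movie, sim$mask)
  expect_equal(st$n_tracks,
               filt$report$n[filt$report$reason == "accepted"])
  expect_equal(sum(st$duration_hist$count), length(st$durations_s))
  # censored tracks are counted in frequency but not the duration mean
  smry <- filt$summary
  n_cens <- sum(smry$status == "accepted" &
                  (smry$censored_start | smry$censored_end))
  expect_equal(length(st$durations_s), st$n_tracks - n_cens)
  expect_equal(st$frequency_per10um2_min,
               patch_frequency(st$n_tracks, sim$mask$area_um2, 89 * 4 / 60))
  g <- glance(st)
  expect_equal(g$n_tracks, st$n_tracks)
  expect_equal(nrow(g), 1L)
})

test_that("crowding correction is the documented fixed point", {
  sim <- simulate_movie(synthetic_spec(rng_seed = 11))
  spots <- detect_movie_spots(sim$movie, sim$mask)
  filt <- filter_tracks(link_tracks(spots), frame_interval_s = 4,
                        n_movie_frames = 89)
  cc <- crowding_corrected_count(filt, sim$mask, 89)
  r_f <- 2 * sqrt((0.6 / (2 * sqrt(2)))^2 + (0.6 / 2.355)^2)
  loss <- 0.5 * (1 - exp(-cc$rho * pi * r_f^2))
  expect_equal(cc$loss, loss, tolerance = 1e-10)
  expect_equal(cc$rho_obs, cc$rho * (1 - cc$loss), tolerance = 1e-8)
  expect_gt(cc$n_corrected, cc$n_counted)
})
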