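test_that("bouton geometry matches analytic disc areas", {
  sp1 <- synthetic_spec(n_boutons = 1, bouton_radius_um = 2,
                        pixel_size_um = 0.1)
  m1 <- make_geometry(sp1)
  expect_lt(abs(m1$area_um2 - 4 * pi) / (4 * pi), 0.02)

  expect_error(make_geometry(synthetic_spec(n_boutons = 0)), "bouton")

  # two tangent discs: union area = sum of disc areas (up to the
  # pixels at the single tangency point)
  sp2 <- synthetic_spec(n_boutons = 2, bouton_radius_um = 2,
                        pixel_size_um = 0.1)
  m2 <- make_geometry(sp2)
  expect_lt(abs(m2$area_um2 - 2 * m1$area_um2), 3 * 0.1^2 + 1e-9)
})

test_that("event sampling is Poisson with the documented rate", {
  # f = 6 / 10 um^2 / min on ~20 um^2 for 5 min -> lambda ~ 60
  sp <- synthetic_spec(n_boutons = 1, bouton_radius_um = sqrt(20 / pi),
                       margin_um = 0.5, event_frequency = 6,
                       frame_interval_s = 4, n_frames = 75)
  mask <- make_geometry(sp)
  lambda <- 6 * (mask$area_um2 / 10) * (75 * 4 / 60)
  counts <- vapply(1:400, function(s) nrow(sample_events(sp, mask, s)),
                   numeric(1))
  se <- sqrt(lambda / 400)
  expect_lt(abs(mean(counts) - lambda), 3 * se)

  # f = 0: always empty
  sp0 <- tiny_spec(event_frequency = 0)
  expect_equal(nrow(sample_events(sp0, make_geometry(sp0), 1)), 0L)

  # durations are always at least one frame
  spd <- tiny_spec(duration_mean_s = 16, frame_interval_s = 4,
                   event_frequency = 20)
  ev <- sample_events(spd, make_geometry(spd), 3)
  expect_true(all(ev$n_frames >= 1L))
})

test_that("rendering is additive with a rectangular temporal profile", {
  sp <- tiny_spec(noise_sigma = 0, shot_noise = FALSE)
  mask <- make_geometry(sp)
  base <- render_movie(sample_events(tiny_spec(event_frequency = 0), mask, 1),
                       mask, sp)
  # no events: every frame identical to the baseline
  expect_equal(base$data[5, , ], base$data[37, , ])

  # one event with a = 1 at a pixel centre: peak = 2B during its life,
  # frames outside the lifetime equal the baseline exactly
  psz <- sp$pixel_size_um
  ctr_px <- round(dim(mask$pixels) / 2)
  ev <- tibble::tibble(event_id = 1L,
                       x_um = (ctr_px[2] - 0.5) * psz,
                       y_um = (ctr_px[1] - 0.5) * psz,
                       start_frame = 4L, n_frames = 4L,
                       duration_s = 16, amplitude = 1 * sp$baseline)
  mv <- render_movie(ev, mask, sp)
  expect_equal(mv$data[5, ctr_px[1], ctr_px[2]], 2 * sp$baseline,
               tolerance = 1e-10)
  expect_equal(mv$data[3, , ], base$data[3, , ])
  expect_equal(mv$data[8, , ], base$data[8, , ])
})

test_that("pixel mode reproduces its degenerate and asymptotic cases", {
  # p = 0: constant movie
  sp0 <- tiny_spec(pixel_mode = TRUE, dynamic_pixel_fraction = 0,
                   noise_sigma = 0, shot_noise = FALSE)
  pm0 <- pixel_mode_movie(sp0)
  expect_equal(pm0$movie$data[1, , ], pm0$movie$data[40, , ])

  # p = 1 with 50% duty cycle: long-run time-mean of mask pixels
  # approaches B * (1 + a/2)
  spd <- synthetic_spec(n_boutons = 1, bouton_radius_um = 0.8,
                        margin_um = 0.5, pixel_mode = TRUE,
                        dynamic_pixel_fraction = 1, amplitude_ratio = 0.6,
                        noise_sigma = 0, shot_noise = FALSE,
                        n_frames = 2000, frame_interval_s = 4,
                        duration_mean_s = 60,
                        pixel_rate_per_min = 0.5 * 60 / 60,  # duty = 0.5
                        edge_blur_um = 0, rng_seed = 2)
  pm <- pixel_mode_movie(spd)
  inner <- pm$mask$pixels
  tm <- apply(pm$movie$data, c(2, 3), mean)[inner]
  # Poisson-start square waves overlap, so realized duty is
  # 1 - exp(-0.5) applied multiplicatively; just check the coarse target
  expect_lt(abs(mean(tm) / (spd$baseline * (1 + 0.6 / 2)) - 1), 0.12)

  # determinism
  pm2 <- pixel_mode_movie(spd)
  expect_identical(pm$movie$data, pm2$movie$data)
})

test_that("noise and bleaching follow the stated model", {
  sp <- tiny_spec(noise_sigma = 0, shot_noise = FALSE, bleach_rate = 0)
  mask <- make_geometry(sp)
  mv <- render_movie(sample_events(tiny_spec(event_frequency = 0), mask, 1),
                     mask, sp)
  expect_identical(apply_noise_and_bleach(mv, sp)$data, mv$data)

  # half-life chosen so the last frame is half the first
  spb <- tiny_spec(noise_sigma = 0, shot_noise = FALSE)
  spb$bleach_rate <- log(2) / ((spb$n_frames - 1) * spb$frame_interval_s)
  dec <- apply_noise_and_bleach(mv, spb)
  expect_equal(mean(dec$data[spb$n_frames, , ]) / mean(dec$data[1, , ]),
               0.5, tolerance = 1e-10)

  # shot noise on a flat B = 100 movie: per-pixel temporal variance ~ B
  flat <- patch_movie(array(100, c(2000, 6, 6)), 0.13, 4)
  sps <- tiny_spec(noise_sigma = 0, shot_noise = TRUE, rng_seed = 4)
  noisy <- apply_noise_and_bleach(flat, sps)
  v <- apply(noisy$data, c(2, 3), stats::var)
  expect_lt(abs(mean(v) - 100) / 100, 0.05)
  expect_error(
    apply_noise_and_bleach(mv, tiny_spec(noise_sigma = -1)), ">= 0")
})

test_that("the generator is deterministic in its seed", {
  a <- simulate_movie(tiny_spec(rng_seed = 33))
  b <- simulate_movie(tiny_spec(rng_seed = 33))
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_movie(tiny_spec(rng_seed = 34))
  expect_false(identical(a$movie$data, c$movie$data))
})

test_that("an isolated noiseless event yields the generating amplitude", {
  fx <- single_event_movie(amplitude_ratio = 0.68)
  spots <- detect_movie_spots(fx$movie, fx$mask)
  filt <- filter_tracks(link_tracks(spots), frame_interval_s = 4,
                        n_movie_frames = n_frames(fx$movie))
  expect_equal(filt$report$n[filt$report$reason == "accepted"], 1L)
  amp <- relative_amplitude(filt$accepted, fx$movie)
  expect_lt(abs(amp - 0.68), 0.05 * 0.68)
})
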