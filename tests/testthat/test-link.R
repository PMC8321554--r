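mk_spots <- function(frame, x, y) {
  tibble::tibble(frame = as.integer(frame), x_um = x, y_um = y,
                 peak_intensity = 100, quality = 50)
}

test_that("linking respects the maximum linking distance", {
  # 0.3 um apart in consecutive frames: one two-spot track
  near <- link_tracks(mk_spots(c(1, 2), c(1.0, 1.3), c(1.0, 1.0)))
  expect_equal(length(unique(near$track_id)), 1L)

  # 0.6 um apart: two one-spot tracks
  far <- link_tracks(mk_spots(c(1, 2), c(1.0, 1.6), c(1.0, 1.0)))
  expect_equal(length(unique(far$track_id)), 2L)
})

test_that("frame-pair assignment matches exhaustive enumeration", {
  set.seed(41)
  for (case in 1:60) {
    n1 <- sample(0:4, 1); n2 <- sample(0:4, 1)
    ax <- runif(n1, 0, 2); ay <- runif(n1, 0, 2)
    bx <- runif(n2, 0, 2); by <- runif(n2, 0, 2)
    got <- linker_match_cost(ax, ay, bx, by, 0.5)
    want <- brute_force_match_cost(ax, ay, bx, by, 0.5)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # two crossing spot pairs specifically
  got <- linker_match_cost(c(1, 1.4), c(1, 1), c(1.35, 1.05), c(1, 1), 0.5)
  want <- brute_force_match_cost(c(1, 1.4), c(1, 1), c(1.35, 1.05),
                                 c(1, 1), 0.5)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("linking is invariant to spot order within frames", {
  set.seed(13)
  spots <- mk_spots(rep(1:6, each = 3),
                    runif(18, 0, 3), runif(18, 0, 3))
  canon <- function(tr) {
    key <- tr |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(sig = paste(sprintf("%d:%.6f:%.6f", .data$frame,
                                           .data$x_um, .data$y_um),
                                   collapse = "|"), .groups = "drop")
    sort(key$sig)
  }
  shuffled <- spots[sample(nrow(spots)), ]
  expect_identical(canon(link_tracks(spots)), canon(link_tracks(shuffled)))
})

test_that("no gap closing: a missed frame terminates the track", {
  sp <- mk_spots(c(1, 2, 4, 5), rep(1, 4), rep(1, 4))
  tr <- link_tracks(sp)
  expect_equal(length(unique(tr$track_id)), 2L)
})

test_that("track filtering applies floor, overlap and stationarity rules", {
  prm <- patch_config()$tracking
  # 3-spot track with min_spots = 4: rejected too_short
  t3 <- link_tracks(mk_spots(1:3, rep(1, 3), rep(1, 3)))
  f3 <- filter_tracks(t3, prm, 4, 10)
  expect_equal(f3$summary$status, "too_short")

  # isolated 10-spot track: accepted
  t10 <- link_tracks(mk_spots(1:10, rep(1, 10), rep(1, 10)))
  f10 <- filter_tracks(t10, prm, 4, 12)
  expect_equal(f10$summary$status, "accepted")

  # two parallel concurrent tracks 0.3 um apart: shorter rejected(overlap)
  par <- rbind(mk_spots(1:8, rep(1, 8), rep(1, 8)),
               mk_spots(3:7, rep(1.3, 5), rep(1, 5)))
  fp <- filter_tracks(link_tracks(par), prm, 4, 10)
  expect_equal(sort(fp$summary$status), c("accepted", "overlap"))
  expect_equal(fp$summary$n_spots[fp$summary$status == "overlap"], 5L)

  # overlap_policy = "both" rejects both members
  prm2 <- prm; prm2$overlap_policy <- "both"
  fb <- filter_tracks(link_tracks(par), prm2, 4, 10)
  expect_equal(unique(fb$summary$status), "overlap")

  # a wandering track (steps ~0.3 um) is rejected as erratic
  wander <- mk_spots(1:8, 1 + 0.3 * (0:7), rep(1, 8))
  fw <- filter_tracks(link_tracks(wander), prm, 4, 10)
  expect_equal(fw$summary$status, "erratic")
})

test_that("censoring flags mark tracks touching the movie boundaries", {
  first <- link_tracks(mk_spots(1:5, rep(1, 5), rep(1, 5)))
  s <- track_summary(first, 4, 20)
  expect_true(s$censored_start)
  expect_false(s$censored_end)
  last <- link_tracks(mk_spots(16:20, rep(1, 5), rep(1, 5)))
  s2 <- track_summary(last, 4, 20)
  expect_false(s2$censored_start)
  expect_true(s2$censored_end)
})

test_that("isolated events map one-to-one onto accepted tracks", {
  # noiseless uniform-baseline movie with well-separated events
  psz <- 0.13
  data <- array(100, c(40, 48, 48))
  ev <- tibble::tibble(
    event_id = 1:4,
    x_um = c(1.3, 3.0, 4.6, 2.1),
    y_um = c(1.6, 3.4, 1.9, 4.6),
    start_frame = c(3L, 10L, 20L, 30L),
    n_frames = c(5L, 8L, 4L, 6L))
  sig <- 0.255 / psz
  for (i in 1:4) {
    cx <- ev$x_um[i] / psz + 0.5
    cy <- ev$y_um[i] / psz + 0.5
    g <- 68 * outer(exp(-(seq_len(48) - cy)^2 / (2 * sig^2)),
                    exp(-(seq_len(48) - cx)^2 / (2 * sig^2)))
    fr <- ev$start_frame[i]:(ev$start_frame[i] + ev$n_frames[i] - 1L)
    for (t in fr) data[t, , ] <- data[t, , ] + g
  }
  mv <- patch_movie(data, psz, 4)
  mask <- patch_mask(matrix(TRUE, 48, 48), psz)
  spots <- detect_movie_spots(mv, mask)
  filt <- filter_tracks(link_tracks(spots), frame_interval_s = 4,
                        n_movie_frames = 40)
  acc <- filt$summary[filt$summary$status == "accepted", ]
  expect_equal(nrow(acc), 4L)
  expect_setequal(acc$n_spots, ev$n_frames)
  expect_setequal(acc$start_frame, ev$start_frame)
})
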