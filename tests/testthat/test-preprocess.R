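test_that("translation registration recovers constructed shifts", {
  sim <- simulate_movie(tiny_spec(rng_seed = 2, n_frames = 6))
  d <- sim$movie$data
  # identical frames: zero shifts
  same <- patch_movie(array(rep(d[1, , ], each = 4), c(4, dim(d)[2], dim(d)[3])),
                      0.13, 4)
  reg0 <- register_translation(same)
  expect_true(all(abs(reg0$shifts$dy_px) < 1e-6))
  expect_true(all(abs(reg0$shifts$dx_px) < 1e-6))

  # constructed integer shift (3, -2)
  d[3, , ] <- actinpatches:::shift_int(d[1, , ], 3, -2,
                                       fill = stats::median(d[1, , ]))
  mv <- patch_movie(d, 0.13, 4)
  reg <- register_translation(mv, max_shift_px = 5)
  expect_lt(abs(reg$shifts$dy_px[3] - 3), 0.2)
  expect_lt(abs(reg$shifts$dx_px[3] + 2), 0.2)

  # pure noise: shifts bounded by max_shift_px (with a clamp warning
  # when the correlation peak sits at the search boundary)
  set.seed(77)
  noise <- patch_movie(array(runif(5 * 32 * 32), c(5, 32, 32)), 0.13, 4)
  regn <- suppressWarnings(register_translation(noise, max_shift_px = 3))
  expect_true(all(abs(regn$shifts$dy_px) <= 3))
  expect_true(all(abs(regn$shifts$dx_px) <= 3))
})

test_that("registration reduces frame-to-frame differences on jittered movies", {
  sim <- simulate_movie(tiny_spec(rng_seed = 12, n_frames = 8,
                                  event_frequency = 2))
  d <- sim$movie$data
  set.seed(5)
  for (t in 2:8) {
    d[t, , ] <- actinpatches:::shift_int(sim$movie$data[t, , ],
                                         sample(-3:3, 1), sample(-3:3, 1),
                                         fill = stats::median(d[t, , ]))
  }
  jit <- patch_movie(d, 0.13, 4)
  reg <- register_translation(jit, max_shift_px = 5)
  fdiff <- function(m) mean(abs(m$data[-1, , ] - m$data[-8, , ]))
  expect_lt(fdiff(reg$movie), fdiff(jit))
})

test_that("rolling-ball subtraction matches a naive morphology oracle", {
  set.seed(21)
  img <- matrix(40 + 5 * runif(15 * 15), 15, 15)
  img[8, 8] <- img[8, 8] + 120
  got <- rolling_ball_subtract(img, 4)
  want <- naive_rolling_ball(img, 4)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("rolling-ball subtraction has the defining properties", {
  # constant image -> all zeros
  expect_true(all(rolling_ball_subtract(matrix(37, 30, 30), 8) == 0))

  # narrow spike on a plateau: spike preserved ~ h, plateau ~ 0
  img <- matrix(50, 40, 40)
  img[19:21, 19:21] <- 50 + 80
  out <- rolling_ball_subtract(img, 10)
  expect_equal(out[20, 20], 80, tolerance = 1)
  expect_lt(max(out[1:10, 1:10]), 1e-9)

  # ramp with radius >= image size: 0 <= output <= input
  ramp <- outer(1:30, 1:30, function(i, j) i + 2 * j)
  out2 <- rolling_ball_subtract(ramp, 40)
  expect_true(all(out2 >= 0))
  expect_true(all(out2 <= ramp))

  # idempotence within tolerance: the ball's cap pokes fractionally into
  # a narrow residual spike, so repeated passes shave < 1% per pass
  once <- rolling_ball_subtract(img, 10)
  twice <- rolling_ball_subtract(once, 10)
  expect_equal(twice, once, tolerance = 0.01)

  expect_error(rolling_ball_subtract(img, 0), "> 0")

  # large radii take the shrink/enlarge path but keep the bounds
  big <- matrix(20, 80, 80); big[40, 40] <- 200
  out3 <- rolling_ball_subtract(big, 50)
  expect_true(all(out3 >= 0) && all(out3 <= big))
  expect_gt(out3[40, 40], 100)
})

test_that("presynaptic mask recovers synthetic geometry", {
  sim <- simulate_movie(synthetic_spec(rng_seed = 7))
  mk <- make_presynaptic_mask(sim$movie, blur_sigma_px = 2,
                              method = "otsu")
  jac <- sum(mk$pixels & sim$mask$pixels) /
    sum(mk$pixels | sim$mask$pixels)
  expect_gte(jac, 0.9)

  # the three automatic methods and the fixed threshold all run
  for (m in c("li", "moments", "fixed:50")) {
    mk2 <- make_presynaptic_mask(sim$movie, 2, m)
    expect_gt(mk2$area_um2, 0)
  }

  # constant movie: no mask
  flat <- patch_movie(array(0, c(3, 16, 16)), 0.13, 4)
  expect_error(make_presynaptic_mask(flat, 2, "otsu"), "empty mask|constant")

  # fixed:0 on a positive movie: full-frame mask
  pos <- patch_movie(array(5, c(3, 16, 16)), 0.13, 4)
  mk3 <- make_presynaptic_mask(pos, 0, "fixed:0")
  expect_true(all(mk3$pixels))
})
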