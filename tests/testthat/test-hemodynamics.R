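test_that("block binning equals naive block averaging", {
  set.seed(60)
  m <- matrix(rnorm(13 * 11), 13, 11)
  b <- awakeretina:::block_bin(m, 4L, 2L)
  expect_equal(dim(b), c(3L, 5L))
  for (i in 1:3) for (j in 1:5)
    expect_equal(b[i, j],
                 mean(m[(4 * i - 3):(4 * i), (2 * j - 1):(2 * j)]),
                 tolerance = 1e-12)
  expect_identical(awakeretina:::block_bin(m), m)
})

test_that("Radon velocimetry recovers signed velocities", {
  for (v in c(10, -10)) {
    sm <- streak_model(velocities = v, density = 2, seed = 61)
    g <- gen_linescan(duration = 0.3, tremor = NULL, streaks = sm,
                      noise_sd = 0.01, seed = 61)
    roi <- g$st$data[1001:1512, ]
    rv <- radon_velocity(roi, g$st$space_scale, g$st$line_rate)
    expect_true(rv$valid)
    expect_true(rv$within_bandwidth)
    expect_equal(sign(rv$velocity_mm_s), sign(v))
    expect_lt(abs(rv$velocity_mm_s - v) / abs(v), 0.05)
  }
})

test_that("pure-noise ROIs are flagged invalid", {
  set.seed(62)
  roi <- matrix(rnorm(128 * 160, 0.5, 0.01), 128, 160)
  rv <- radon_velocity(roi)
  expect_false(rv$valid)
  expect_lt(rv$quality, radon_config()$quality_floor)
})

test_that("velocity time courses have the documented shape and stride", {
  sm <- streak_model(velocities = 8, density = 2, seed = 63)
  g <- gen_linescan(duration = 0.2, tremor = NULL, streaks = sm,
                    noise_sd = 0.01, seed = 63)
  cfg <- radon_config(roi_time = 128, roi_overlap = 0.5)
  ser <- velocity_timecourse(g$st, cfg)
  stride <- 64L
  expect_s3_class(ser, "cell_velocity_series")
  expect_equal(nrow(ser), (nrow(g$st$data) - 128L) %/% stride + 1L)
  expect_equal(attr(ser, "stride_s"), stride / g$st$line_rate)
  expect_true(all(is.finite(ser$velocity_interp)))
  expect_gt(mean(ser$valid), 0.8)
  short <- space_time_image(g$st$data[1:300, ])
  expect_error(velocity_timecourse(short, cfg), "8 ROIs")
})

test_that("heart rate reads the pulsatility frequency in Hz and per minute", {
  stride_s <- 64 / 15000
  n <- 1024
  t <- (seq_len(n) - 1) * stride_s
  ser <- data.frame(valid = rep(TRUE, n),
                    velocity_interp = 10 + 3 * sin(2 * pi * 2 * t))
  attr(ser, "stride_s") <- stride_s
  hr <- heart_rate(ser)
  expect_true(hr$detected)
  expect_equal(hr$freq_hz, 2, tolerance = 0.1)
  expect_equal(hr$per_minute, hr$freq_hz * 60)
  expect_identical(hz_to_per_minute(2), 120)
  flat <- ser; flat$velocity_interp <- rep(10, n)
  attr(flat, "stride_s") <- stride_s
  expect_false(heart_rate(flat)$detected)
})

test_that("motion contrast is zero for a static video", {
  arr <- array(0.4, dim = c(5, 6, 7))
  expect_equal(motion_contrast(arr), matrix(0, 6, 7))
  arr[, 3, 4] <- seq_len(5)
  mc <- motion_contrast(arr)
  expect_equal(mc[3, 4], sd(1:5))
})

test_that("vessel diameter is the interpolated FWHM of the profile", {
  # trapezoid with the half-max level hit exactly at samples 25 (rising,
  # value 0.5) and 54 (falling, value 0.5): FWHM = 29 samples
  p <- c(rep(0, 20), seq(0, 1, length.out = 11)[-1],
         rep(1, 19), seq(1, 0, length.out = 11)[-1], rep(0, 20))
  expect_equal(vessel_diameter(NULL, profile = p, px_scale = 2), 58,
               tolerance = 1e-9)
  expect_error(vessel_diameter(NULL, profile = rep(0.3, 50)),
               "no dominant vessel peak")
})

test_that("flow arithmetic reproduces the worked unit conversions", {
  expect_equal(flow_rate(1, 50), 1 * pi * 25^2 * 6e-5, tolerance = 1e-12)
  expect_equal(round(flow_rate(1, 50), 4), 0.1178)
  expect_equal(percent_reduction(1.56, 0.89), 100 * (1 - 0.89 / 1.56))
  expect_error(flow_rate(-1, 50))
})

test_that("power-law fitting is exact on noiseless data and predicts", {
  d <- c(10, 20, 30, 50, 80)
  rec <- data.frame(diameter = d, flow = 0.003 * d^2.5)
  fit <- fit_flow_diameter(rec)
  expect_equal(fit$a, 0.003, tolerance = 1e-10)
  expect_equal(fit$b, 2.5, tolerance = 1e-10)
  expect_equal(fit$sigma_log, 0, tolerance = 1e-10)
  expect_equal(predict(fit, 40), 0.003 * 40^2.5, tolerance = 1e-8)
  expect_output(print(fit), "flow-diameter model")
  expect_error(fit_flow_diameter(data.frame(diameter = c(-1, 2, 3),
                                            flow = c(1, 2, 3))), "positive")
  expect_error(fit_flow_diameter(data.frame(diameter = c(10, 10, 10),
                                            flow = c(1, 2, 3))), "distinct")
})
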