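test_that("seeded RNG helpers are deterministic and leave no trace", {
  set.seed(99)
  before <- .Random.seed
  a <- awakeretina:::with_seed(123, rnorm(5))
  expect_identical(.Random.seed, before)
  b <- awakeretina:::with_seed(123, rnorm(5))
  expect_identical(a, b)

  s1 <- awakeretina:::substream_seed(1, "alpha")
  s2 <- awakeretina:::substream_seed(1, "beta")
  s3 <- awakeretina:::substream_seed(2, "alpha")
  expect_false(s1 == s2)
  expect_false(s1 == s3)
  expect_identical(s1, awakeretina:::substream_seed(1, "alpha"))
  expect_lt(max(s1, s2, s3), 2^31)
  expect_gte(min(s1, s2, s3), 0)
})

test_that("band-limited tremor stays in band with the requested RMS", {
  tm <- tremor_model(rms_amplitude = 2, seed = 4)
  fs <- 15000
  x <- gen_tremor_trace(tm, 30000, fs)
  expect_length(x, 30000)
  # remove the deterministic respiration/cardiac lines, check tremor RMS
  tm0 <- tremor_model(rms_amplitude = 2, resp_amp = 0, cardiac_amp = 0,
                      seed = 4)
  x0 <- gen_tremor_trace(tm0, 30000, fs)
  expect_equal(sd(x0), 2, tolerance = 0.05)
  spec <- motion_spectrum(x0, fs)
  inband <- band_power(spec, 30, 200)
  outband <- band_power(spec, 300, 1000)
  expect_gt(inband / outband, 1e3)
  expect_error(gen_tremor_trace(tm, 100, 300), "Nyquist")
})

test_that("pupil scenes render a dark ellipse with usable ground truth", {
  sc <- pupil_scene(seed = 6)
  g <- gen_pupil_video(sc, n_frames = 4)
  expect_equal(n_frames(g$video), 4)
  expect_equal(nrow(g$truth), 4)
  fr <- get_frame(g$video, 1)
  inside <- fr[round(g$truth$cy[1]), round(g$truth$cx[1])]
  expect_lt(inside, mean(fr))  # pupil darker than the speckle background
  expect_error(pupil_scene(axes = c(200, 150)), "larger than the frame")
})

test_that("blink intervals darken pupil frames (list and matrix forms)", {
  for (iv in list(list(c(0.1, 0.35)), matrix(c(0.1, 0.35), 1))) {
    sc <- pupil_scene(blink_intervals = iv, seed = 7)
    g <- gen_pupil_video(sc, n_frames = 5)
    expect_true(any(g$truth$blink))
    means <- apply(g$video$frames, 1, mean)
    expect_lt(mean(means[g$truth$blink]), mean(means[!g$truth$blink]))
  }
})

test_that("SLO video truth is self-consistent and bounded by overlap", {
  mot <- cbind(seq(0, 0.5, length.out = 5), seq(0, -0.4, length.out = 5))
  g <- gen_slo_video(mot, seed = 8)
  expect_equal(g$truth$dx_px, g$truth$dx_deg / 0.1, tolerance = 1e-9)
  big <- cbind(c(0, 50), c(0, 0))  # 500 px >> frame: overlap broken
  expect_error(gen_slo_video(big, seed = 8), "overlap")
})

test_that("line-scan generator enforces geometry and returns truth", {
  expect_error(gen_linescan(duration = 0.05), "2048")
  expect_error(gen_linescan(duration = 0.2, tremor = rep(60, 3000)),
               "leaves the field")
  sm <- streak_model(velocities = c(5, -5), n_streaks = 6, seed = 9)
  g <- gen_linescan(duration = 0.2, tremor = NULL, streaks = sm, seed = 9)
  expect_s3_class(g$st, "space_time_image")
  expect_equal(nrow(g$truth), nrow(g$st$data))
  expect_equal(nrow(g$streak_truth), 6)
  expect_setequal(unique(g$streak_truth$velocity), c(5, -5))
  expect_error(streak_model(velocities = 2000), "velocit")
})

test_that("OCT volumes carry boundary truth consistent with thickness", {
  tmap <- matrix(200, 3, 40)
  g <- gen_oct_volume(tmap, axial_scale = 2, seed = 10)
  expect_equal(dim(g$volume$data), c(3, 256, 40))
  sep_px <- g$truth$osrpe_px - g$truth$ilm_px
  expect_equal(sep_px * 2, tmap, tolerance = 1e-9, ignore_attr = TRUE)
  expect_output(print(g$volume), "oct_volume")
})

test_that("quadrature generator refuses aliasing sample rates", {
  expect_error(gen_quadrature(rep(1, 100), sample_rate = 1000), "aliasing")
  q <- gen_quadrature(rep(0.1, 20000), sample_rate = 20000)
  s <- q$A * 2 + q$B
  expect_true(all(s %in% 0:3))
})
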