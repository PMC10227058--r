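test_that("texture STD filter matches the naive windowed-SD oracle", {
  set.seed(30)
  fr <- matrix(runif(18 * 15), 18, 15)
  expect_lt(max(abs(std_filter(fr, 5) - std_filter_oracle(fr, 5))), 1e-10)
})

test_that("direct ellipse fit recovers rotated ellipses from points", {
  set.seed(31)
  for (k in 1:5) {
    cx <- runif(1, -5, 5); cy <- runif(1, -5, 5)
    a <- runif(1, 4, 9); b <- runif(1, 2, 4)
    phi <- runif(1, 0, 180)
    th <- seq(0, 2 * pi, length.out = 40)
    p <- phi * pi / 180
    x <- cx + a * cos(th) * cos(p) - b * sin(th) * sin(p)
    y <- cy + a * cos(th) * sin(p) + b * sin(th) * cos(p)
    e <- awakeretina:::fit_ellipse(x, y)
    expect_equal(e$cx, cx, tolerance = 1e-6)
    expect_equal(e$cy, cy, tolerance = 1e-6)
    expect_equal(sort(c(e$a, e$b)), sort(c(a, b)), tolerance = 1e-6)
  }
})

test_that("pupil segmentation finds the low-texture ellipse", {
  sc <- pupil_scene(seed = 32)
  g <- gen_pupil_video(sc, n_frames = 1)
  r <- segment_pupil(get_frame(g$video, 1))
  expect_false(is.null(r))
  expect_lt(abs(r$cx - g$truth$cx[1]), 2)
  expect_lt(abs(r$cy - g$truth$cy[1]), 2)
  expect_lt(abs(r$a - g$truth$a[1]) / g$truth$a[1], 0.15)
})

test_that("tracking follows a drifting pupil within 2 px", {
  sc <- pupil_scene(drift = c(0.4, 0.2), seed = 33)
  g <- gen_pupil_video(sc, n_frames = 10)
  tr <- track_pupil(g$video)
  expect_true(all(tr$valid))
  err <- sqrt((tr$cx - g$truth$cx)^2 + (tr$cy - g$truth$cy)^2)
  expect_lt(max(err), 2)
})

test_that("logic gates invalidate impossible jumps", {
  sc <- pupil_scene(seed = 34)
  g <- gen_pupil_video(sc, n_frames = 6)
  raw <- track_pupil(g$video, gate = FALSE)
  raw$cx[4] <- raw$cx[4] + 200  # teleporting center
  gated <- gate_trace(raw)
  expect_false(gated$valid[4])
  expect_true(gated$valid[3])
})

test_that("blink frames yield no pupil and are invalid", {
  sc <- pupil_scene(blink_intervals = list(c(0.2, 0.5)), seed = 35)
  g <- gen_pupil_video(sc, n_frames = 6)
  tr <- track_pupil(g$video)
  expect_true(all(!tr$valid[g$truth$blink]))
})

test_that("polygon-in-circle area matches closed forms", {
  # concentric circle-in-circle through the ellipse mapping
  a_small <- awakeretina:::circle_ellipse_intersection(
    0, 0, 3, 0, 0, 5, 5, 0)
  expect_equal(a_small, pi * 9, tolerance = 1e-4)
  # beam fully inside an ellipse
  full <- awakeretina:::circle_ellipse_intersection(1, 0, 2, 0, 0, 8, 6, 0)
  expect_equal(full, pi * 4, tolerance = 1e-4)
  # offset circle vs circular pupil: circle-circle lens closed form
  for (d in c(0.5, 2, 4.5)) {
    got <- awakeretina:::circle_ellipse_intersection(d, 0, 3, 0, 0, 2.5, 2.5, 0)
    expect_equal(got, lens_area(d, 3, 2.5), tolerance = 1e-4)
  }
  # disjoint
  expect_equal(awakeretina:::circle_ellipse_intersection(20, 0, 3, 0, 0, 2, 2, 0),
               0, tolerance = 1e-6)
})

test_that("smaller beams clip less on the same pupil trace", {
  sc <- pupil_scene(drift = c(0.3, 0.15), seed = 36)
  g <- gen_pupil_video(sc, n_frames = 8)
  tr <- track_pupil(g$video)
  r20 <- beam_clipping(tr, beam_spec(2.0, sc$mm_per_px))
  r16 <- beam_clipping(tr, beam_spec(1.6, sc$mm_per_px))
  expect_gt(r20$mean_clipped_pct, r16$mean_clipped_pct)
  expect_gte(r16$frac_unclipped, r20$frac_unclipped)
  expect_output(print(r20), "clipping_report")
  b <- bin_1s(r20)
  expect_true(all(c("t_start", "mean") %in% names(b)))
})
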