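make_slo <- function(n = 40, sd_step = 0.05, blink_frames = NULL, seed = 40) {
  set.seed(seed)
  mot <- cbind(cumsum(rnorm(n, 0, sd_step)), cumsum(rnorm(n, 0, sd_step)))
  gen_slo_video(mot, blink_frames = blink_frames, seed = seed)
}

test_that("template sets require exactly three in-bounds rectangles", {
  g <- make_slo(4)
  expect_error(template_set(g$video, list(c(1, 1, 10, 10))), "3 templates")
  expect_error(
    template_set(g$video, list(c(1, 1, 10, 10), c(1, 1, 10, 10),
                               c(200, 200, 40, 40))),
    "inside the reference")
})

test_that("the 60% rule finds blink frames and groups events", {
  g <- make_slo(30, blink_frames = c(12, 13, 14), seed = 41)
  bl <- detect_blinks(g$video)
  expect_identical(which(bl$flags), 12:14)
  expect_equal(nrow(bl$events), 1)
  expect_equal(bl$events$n_frames, 3)
  expect_equal(bl$events$duration_s * 1000, blink_duration_ms(3),
               tolerance = 1e-9)
  # gain invariance: scaling intensities must not change the flags
  v2 <- g$video
  v2$frames <- v2$frames * 0.37
  expect_identical(detect_blinks(v2)$flags, bl$flags)
})

test_that("gaze tracking recovers the injected motion to sub-pixel", {
  g <- make_slo(40, seed = 42)
  tpl <- template_set(g$video, list(c(20, 20, 40, 40), c(90, 30, 40, 40),
                                    c(40, 90, 40, 40)))
  tr <- track_gaze(g$video, tpl)
  v <- tr$valid
  expect_gt(sum(v), 35)
  tx <- g$truth$dx_deg - g$truth$dx_deg[1]
  ty <- g$truth$dy_deg - g$truth$dy_deg[1]
  rmse_px <- sqrt(mean(((tr$dx_deg[v] - tx[v])^2 +
                          (tr$dy_deg[v] - ty[v])^2))) / g$video$pixel_scale
  expect_lt(rmse_px, 0.5)
})

test_that("blink frames and their neighbors are not tracked", {
  g <- make_slo(30, blink_frames = c(15, 16), seed = 43)
  tr <- track_gaze(g$video, template_set(g$video, list(
    c(20, 20, 40, 40), c(90, 30, 40, 40), c(40, 90, 40, 40))))
  expect_true(all(!tr$valid[14:17]))
  expect_true(tr$valid[13] && tr$valid[18])
})

test_that("window normalization re-references offsets and scores persistence", {
  g <- make_slo(40, seed = 44)
  tr <- track_gaze(g$video, template_set(g$video, list(
    c(20, 20, 40, 40), c(90, 30, 40, 40), c(40, 90, 40, 40))))
  wn <- window_normalize(tr, window = 2, radius_deg = 5)
  v <- wn$trace$valid
  expect_true(all(is.finite(wn$trace$dx_norm[v])))
  expect_equal(wn$fraction_within, 1)
  # per-window means of the normalized trace are ~0
  wid <- floor(wn$trace$t / 2)
  for (w in unique(wid[v]))
    expect_equal(mean(wn$trace$dx_norm[v & wid == w]), 0, tolerance = 1e-9)
  expect_error(window_normalize(tr, window = 100), "shorter")
})

test_that("gaze velocity and gaze-gait correlation behave sanely", {
  g <- make_slo(40, seed = 45)
  tr <- track_gaze(g$video, template_set(g$video, list(
    c(20, 20, 40, 40), c(90, 30, 40, 40), c(40, 90, 40, 40))))
  gv <- gaze_velocity(tr)
  expect_equal(nrow(gv), nrow(tr))
  expect_true(all(gv$speed_deg_s[is.finite(gv$speed_deg_s)] >= 0))

  # constructed gait bins: zero variance gives the degenerate r = 0 path
  gait0 <- data.frame(t_start = 0:4, speed = rep(0.5, 5))
  cc <- correlate_gaze_gait(tr, gait0)
  expect_true(cc$degenerate)
  expect_identical(cc$r, 0)
  expect_error(correlate_gaze_gait(tr, data.frame(t_start = 100:104,
                                                  speed = 1:5)),
               "3 paired")
})
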