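test_that("video_frames validates input and synthesizes timestamps", {
  arr <- array(runif(5 * 8 * 9), c(5, 8, 9))
  v <- video_frames(arr, frame_rate = 10)
  expect_s3_class(v, "video_frames")
  expect_equal(n_frames(v), 5)
  expect_equal(v$timestamps, (0:4) / 10)
  expect_equal(dim(get_frame(v, 3)), c(8, 9))

  expect_error(video_frames(matrix(0, 2, 2), 10), "time x rows x cols")
  expect_error(video_frames(arr, 0), "frame_rate")
  expect_error(video_frames(arr, 10, timestamps = rev((0:4) / 10)),
               "strictly increasing")
  expect_error(video_frames(list(matrix(0, 2, 2), matrix(0, 3, 3)), 10),
               "same shape")
})

test_that("normalize01 maps to [0,1], is idempotent and zeros constants", {
  set.seed(1)
  for (k in 1:10) {
    x <- array(rnorm(60, sd = 10^runif(1, -3, 3)), c(3, 4, 5))
    y <- normalize01(x)
    expect_gte(min(y), 0)
    expect_lte(max(y), 1)
    expect_equal(normalize01(y), y, tolerance = 1e-12)
  }
  expect_true(all(normalize01(array(7, c(2, 2, 2))) == 0))
})

test_that("TIFF video round trip preserves frames to 16-bit precision", {
  arr <- array(runif(3 * 16 * 16), c(3, 16, 16))
  v <- video_frames(arr, frame_rate = 8.8, normalize = TRUE)
  path <- tempfile(fileext = ".tif")
  write_video(v, path)
  v2 <- read_video(path, frame_rate = 8.8)
  expect_equal(n_frames(v2), 3)
  expect_lt(max(abs(v2$frames - v$frames)), 2 / 65535)
})

test_that("read_video rejects AVI and missing files", {
  expect_error(read_video("nope.tif", 10), "cannot read")
  avi <- tempfile(fileext = ".avi")
  writeLines("x", avi)
  expect_error(read_video(avi, 10), "AVI")
})

test_that("trace CSV round trip restores values and NA gaps", {
  df <- data.frame(t = c(0, 0.1, 0.2), v = c(1.25, NA, -3.5),
                   ok = c(TRUE, FALSE, TRUE))
  path <- tempfile(fileext = ".csv")
  write_trace(df, path)
  back <- read_trace(path)
  expect_equal(back$v, df$v, tolerance = 1e-9)
  expect_true(is.na(back$v[2]))
  expect_error(write_trace(data.frame(), tempfile()), "non-empty")
})

test_that("retinal scale converts 5.95 um to 10.50 arcmin and inverts", {
  expect_equal(um_to_arcmin(5.95), 10.5, tolerance = 1e-3)
  set.seed(2)
  x <- runif(20, 0, 50)
  expect_equal(arcmin_to_um(um_to_arcmin(x)), x, tolerance = 1e-12)
  sc <- scale_model(30)
  expect_equal(arcmin_to_um(60, sc), 30)
  expect_error(scale_model(-1), "positive")
})

test_that("parabolic peak refinement recovers fractional vertices exactly", {
  set.seed(3)
  for (k in 1:25) {
    d0 <- runif(1, -0.49, 0.49)
    a <- -runif(1, 0.5, 3)
    y <- a * ((-1:1) - d0)^2 + rnorm(1)
    expect_equal(awakeretina:::peak_refine(y), d0, tolerance = 1e-10)
  }
  # flat or non-concave data refines to zero rather than diverging
  expect_equal(awakeretina:::peak_refine(c(1, 1, 1)), 0)
  expect_equal(awakeretina:::peak_refine(c(5, 1, 5)), 0)
})

test_that("time binning keeps empty bins as NA and counts samples", {
  t <- c(0.1, 0.4, 2.3, 2.9)
  x <- c(1, 3, 10, NA)
  b <- awakeretina:::bin_by_time(t, x, bin_width = 1, t0 = 0)
  expect_equal(b$t_start, c(0, 1, 2))
  expect_equal(b$mean, c(2, NA, 10))
  expect_equal(b$n, c(2L, 0L, 2L))
  expect_equal(b$n_valid, c(2L, 0L, 1L))
})

test_that("space_time_image validates geometry", {
  st <- space_time_image(matrix(0, 4, 5), line_rate = 15000, theta = 90)
  expect_s3_class(st, "space_time_image")
  expect_output(print(st), "15000")
  expect_error(space_time_image(matrix(0, 4, 5), theta = 0), "theta")
  expect_error(space_time_image(matrix(0, 4, 5), line_rate = -1), "line_rate")
})
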