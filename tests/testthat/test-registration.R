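test_that("FFT-based NCC map matches the brute-force correlation oracle", {
  set.seed(10)
  img <- matrix(runif(24 * 26), 24, 26)
  tpl <- img[5:13, 7:15]
  fast <- ncc_match(img, tpl)
  slow <- ncc_oracle(img, tpl)
  expect_equal(dim(fast), dim(slow))
  expect_lt(max(abs(fast - slow)), 1e-8)
  expect_equal(which.max(fast), which.max(slow))
  expect_equal(max(fast), 1, tolerance = 1e-8)
})

test_that("NCC map stays within [-1, 1] and zeros flat windows", {
  set.seed(11)
  img <- matrix(runif(30 * 30), 30, 30)
  img[1:12, 1:12] <- 0.5  # flat region
  tpl <- matrix(runif(5 * 5), 5, 5)
  m <- ncc_match(img, tpl)
  expect_true(all(m >= -1 & m <= 1))
  expect_equal(m[3, 3], 0)  # zero-variance window
  expect_error(ncc_match(tpl, img), "larger than image")
})

test_that("best_shift recovers known integer and fractional offsets", {
  set.seed(12)
  base <- matrix(runif(90 * 90), 90, 90)
  base <- presmooth(base, 1.5)
  ref <- base[21:70, 21:70]
  mov <- base[(21 - 3):(70 - 3), (21 + 2):(70 + 2)]  # content down 3, left 2
  r <- best_shift(mov, ref, search_radius = 10)
  expect_equal(r$dx, -2, tolerance = 0.05)
  expect_equal(r$dy, 3, tolerance = 0.05)
  expect_gt(r$ncc, 0.99)
  # fractional shift via bilinear resampling
  mov2 <- awakeretina:::shift_image(ref, 1.5, -0.5)
  r2 <- best_shift(mov2, ref, search_radius = 10)
  expect_equal(r2$dx, 1.5, tolerance = 0.2)
  expect_equal(r2$dy, -0.5, tolerance = 0.2)
})

test_that("rigid registration equals exhaustive shift search", {
  set.seed(13)
  base <- presmooth(matrix(runif(70 * 70), 70, 70), 1)
  ref <- base[11:60, 11:60]
  mov <- base[(11 - 4):(60 - 4), (11 - 5):(60 - 5)]  # dy = +4? content up 4, left... see below
  r <- best_shift(mov, ref, search_radius = 8, subpixel = FALSE)
  # oracle: slide the central crop over all +/- 8 shifts, maximize cor()
  crop <- mov[9:42, 9:42]
  best <- c(ncc = -Inf, dx = NA, dy = NA)
  for (dy in -8:8) {
    for (dx in -8:8) {
      rows <- (9 - dy):(42 - dy); cols <- (9 - dx):(42 - dx)
      if (min(rows) < 1 || max(rows) > 50 || min(cols) < 1 || max(cols) > 50)
        next
      cc <- cor(as.numeric(crop), as.numeric(ref[rows, cols]))
      if (cc > best["ncc"]) best <- c(ncc = cc, dx = dx, dy = dy)
    }
  }
  expect_equal(r$dx, unname(best["dx"]))
  expect_equal(r$dy, unname(best["dy"]))
  expect_equal(r$ncc, unname(best["ncc"]), tolerance = 1e-6)
})

test_that("strip sampling rate is 468 Hz printed, 468.75 Hz exact", {
  expect_identical(strip_sampling_rate(15000, 32), 468)
  expect_equal(strip_sampling_rate(15000, 32, exact = TRUE), 468.75)
})

test_that("strip registration recovers per-strip shear", {
  g <- gen_aoslo_video(n_frames = 2, shear_amp_px = 3, seed = 20)
  cfg <- registration_config(search_radius = 16)
  ref <- get_frame(g$video, 1)
  fr <- get_frame(g$video, 2)
  tr <- register_strips(fr, ref, cfg)
  expect_true(all(tr$accepted))
  sw <- cfg$strip_width
  grp <- rep(seq_len(nrow(tr)), each = sw)
  s2 <- tapply(g$shear_px[2, seq_len(nrow(tr) * sw)], grp, mean)
  s1 <- tapply(g$shear_px[1, seq_len(nrow(tr) * sw)], grp, mean)
  # the strip-mean shear is only an approximation of what NCC locks onto
  # within a strip, so allow sub-pixel scatter around it
  expect_lt(mean(abs(tr$dx - (s2 - s1))), 0.5)
  expect_lt(max(abs(tr$dx - (s2 - s1))), 1.5)
})

test_that("failed strips are rejected by the NCC threshold", {
  set.seed(21)
  ref <- presmooth(matrix(runif(64 * 64), 64, 64), 1)
  fr <- ref
  fr[1:32, ] <- matrix(runif(32 * 64), 32, 64)  # first strip decorrelated
  tr <- register_strips(fr, ref, registration_config(search_radius = 8))
  expect_false(tr$accepted[1])
  expect_true(tr$accepted[2])
})

test_that("registered strip rendering is sharper than frame, than none", {
  g <- gen_aoslo_video(n_frames = 6, shear_amp_px = 4, seed = 22)
  cfg <- registration_config(search_radius = 24)
  ge <- vapply(c("none", "frame", "strip"), function(m)
    gradient_energy(render_registered(g$video, cfg, mode = m)$average),
    numeric(1))
  expect_lt(ge[["none"]], ge[["frame"]])
  expect_lt(ge[["frame"]], ge[["strip"]])
})

test_that("gradient energy ignores missing pixels", {
  m <- matrix(c(0, 1, NA, 1), 2, 2)
  expect_true(is.finite(gradient_energy(m)))
  expect_equal(gradient_energy(matrix(0.3, 5, 5)), 0)
})

test_that("presmooth preserves the mean and is identity at sigma 0", {
  set.seed(23)
  img <- matrix(runif(40 * 40), 40, 40)
  expect_identical(presmooth(img, 0), img)
  sm <- presmooth(img, 3)
  expect_equal(mean(sm), mean(img), tolerance = 1e-3)
  expect_lt(sd(sm), sd(img))
})
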