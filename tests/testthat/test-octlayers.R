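test_that("DP boundary path equals exhaustive enumeration on small bands", {
  set.seed(70)
  for (k in 1:4) {
    bs <- matrix(runif(8 * 8), 8, 8)
    for (pol in c("dark_to_bright", "bright_to_dark")) {
      g <- awakeretina:::polarity_gradient(bs, pol)
      got <- segment_boundary(bs, pol)
      want <- dp_oracle(g)
      expect_identical(got$path, as.integer(want$path))
    }
  }
})

test_that("forbidden nodes are respected and match the oracle", {
  set.seed(71)
  bs <- matrix(runif(8 * 8), 8, 8)
  forb <- matrix(FALSE, 8, 8)
  forb[1:4, ] <- TRUE  # confine the path to the lower half
  got <- segment_boundary(bs, "dark_to_bright", forbidden = forb)
  expect_true(all(got$path >= 5))
  g <- awakeretina:::polarity_gradient(bs, "dark_to_bright")
  g[forb] <- -1e6
  expect_identical(got$path, as.integer(dp_oracle(g)$path))
})

test_that("flat B-scans degrade to a flagged flat path", {
  bs <- matrix(0.5, 10, 12)
  expect_warning(r <- segment_boundary(bs), "zero gradient")
  expect_true(r$degenerate)
  expect_identical(r$path, rep(5L, 12))
})

test_that("volume segmentation recovers both boundaries accurately", {
  tmap <- matrix(200, 4, 48) + outer(rep(0, 4), sin(seq(0, pi, length.out = 48)) * 10)
  g <- gen_oct_volume(tmap, seed = 72)
  b <- segment_volume(g$volume)
  expect_lt(mean(abs(b$ilm_px - g$truth$ilm_px)), 1)
  expect_lt(mean(abs(b$osrpe_px - g$truth$osrpe_px)), 1)
  expect_true(all(b$osrpe_px > b$ilm_px))
})

test_that("thickness maps mask the optic disc and keep it out of stats", {
  tmap <- matrix(210, 5, 64)
  g <- gen_oct_volume(tmap, seed = 73)
  b <- segment_volume(g$volume)
  m <- trt_map(b, g$volume)
  expect_gt(sum(m$mask), 0)
  expect_true(all(is.na(m$trt_um[m$mask])))
  expect_equal(mean(m$trt_um, na.rm = TRUE), 210, tolerance = 2)
  # the mask lies within the requested diameter of the disc center
  dc <- g$volume$disc_center
  D <- sqrt(outer((m$y_deg - dc[2])^2, (m$x_deg - dc[1])^2, "+"))
  expect_true(all(D[m$mask] <= 4 + 1e-9))
  expect_true(all(D[!m$mask] > 4))
  expect_output(print(m), "thickness_map")
})

test_that("longitudinal change reports the injected thickening", {
  tmap <- matrix(205, 5, 64)
  g0 <- gen_oct_volume(tmap, seed = 74)
  g1 <- gen_oct_volume(tmap + 8, seed = 75)
  m0 <- trt_map(segment_volume(g0$volume), g0$volume)
  m1 <- trt_map(segment_volume(g1$volume), g1$volume)
  ch <- trt_change(m1, m0)
  expect_equal(ch$mean_change_um, 8, tolerance = 1)
  expect_equal(ch$pct_change, 100 * 8 / 205, tolerance = 0.5)
  expect_equal(nrow(ch$ecc_bins), 3)
  # annuli fully under the disc mask have no cells and stay NA
  covered <- ch$ecc_bins$n > 0
  expect_true(any(covered))
  expect_true(all(is.finite(ch$ecc_bins$mean_change_um[covered])))
  small <- gen_oct_volume(matrix(205, 3, 32), seed = 76)
  ms <- trt_map(segment_volume(small$volume), small$volume)
  expect_error(trt_change(m1, ms), "same grid")
})
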