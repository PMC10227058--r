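test_that("shear extraction recovers an injected sinusoid trace", {
  lr <- 15000
  n <- round(0.6 * lr)
  t <- (seq_len(n) - 1) / lr
  w1 <- 3 * sin(2 * pi * 60 * t)
  g <- gen_linescan(duration = 0.6, tremor = w1, noise_sd = 0.02, seed = 50)
  tr <- extract_shear(g$st, seed = 50)
  expect_equal(attr(tr, "sample_rate"), 468.75)
  truth <- tapply(g$truth$w1_um[seq_len(nrow(tr) * 32)],
                  rep(seq_len(nrow(tr)), each = 32), mean)
  v <- tr$valid
  expect_gt(mean(v), 0.9)
  resid <- tr$w1_um[v] - (truth[v] - mean(truth[v]))
  expect_lt(sd(resid), 0.3)
})

test_that("extraction fails loudly without a vessel band", {
  flat <- space_time_image(matrix(0.5, 4096, 160) +
                             matrix(rnorm(4096 * 160, 0, 0.005), 4096, 160))
  expect_error(extract_shear(flat), "no vessel band")
  tiny <- gen_linescan(duration = 0.15, seed = 51)$st
  expect_error(extract_shear(tiny, n_refs = 100), "n_refs")
})

test_that("orthogonal projection applies |w1| = |v| sin(theta)", {
  df <- data.frame(v_um = c(-2, 0, 4))
  out <- project_orthogonal(df, theta = 30)
  expect_equal(out$w1_um, df$v_um * 0.5, tolerance = 1e-12)
  out90 <- project_orthogonal(df, theta = 90)
  expect_equal(out90$w1_um, df$v_um)
  expect_warning(project_orthogonal(df, theta = 5), "poorly conditioned")
  expect_error(project_orthogonal(df), "theta")
})

test_that("the high-pass filter removes drift and keeps the tremor band", {
  fs <- 468.75
  t <- (0:4095) / fs
  slow <- 10 * sin(2 * pi * 1 * t)
  fast <- 2 * sin(2 * pi * 80 * t)
  hp <- highpass(slow + fast, fs, cutoff = 30)
  mid <- 500:3500  # away from filter edge transients
  expect_lt(sd(hp[mid] - fast[mid]), 0.1)
  expect_error(highpass(fast, fs = 50, cutoff = 30), "twice the cutoff")
  expect_equal(highpass(rep(3, 100), fs, 30), rep(0, 100))
})

test_that("Welch spectrum concentrates power at the injected frequency", {
  fs <- 1000
  t <- (0:8191) / fs
  x <- sin(2 * pi * 123.4 * t) + rnorm(8192, 0, 0.1)
  spec <- motion_spectrum(x, fs)
  pk <- find_spectral_peaks(spec, 50, 400)
  expect_equal(pk$freq[1], 123.4, tolerance = 0.3)
  # total power approximates the series variance (Parseval)
  df <- spec$freq[2] - spec$freq[1]
  expect_equal(sum(spec$power) * df, var(x), tolerance = 0.1)
  expect_error(motion_spectrum(rnorm(10), fs), "too short")
})

test_that("tremor amplitude statistics agree on a pure sinusoid", {
  fs <- 468.75
  t <- (0:8191) / fs
  x <- 4 * sin(2 * pi * 100 * t)
  for (m in c("rectified_mean", "rms", "p2p")) {
    st <- tremor_stats(x, fs = fs, method = m)
    expect_equal(st$amplitude_um, 4, tolerance = 0.05)
  }
  st <- tremor_stats(x, fs = fs)
  expect_equal(st$amplitude_arcmin, um_to_arcmin(st$amplitude_um))
})

test_that("respiration and cardiac lines appear at 2 and 9 Hz", {
  tm <- tremor_model(seed = 52)
  g <- gen_linescan(duration = 2.2, tremor = tm, seed = 52)
  tr <- extract_shear(g$st, seed = 52)
  spec <- motion_spectrum(tr$w1_um, attr(tr, "sample_rate"))
  pk <- find_spectral_peaks(spec, 1, 15, prominence = 3)
  expect_gte(nrow(pk), 2)
  two <- sort(pk$freq[1:2])
  expect_equal(two[1], 2, tolerance = 0.3)
  expect_equal(two[2], 9, tolerance = 0.3)
})
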