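# High-frequency eye-motion (micro-tremor) extraction from 15 kHz
# line-scan space-time images, and spectral characterization.
#
# The vessel profile in a space-time image is sheared line-by-line by eye
# motion; 1-d cross-correlation of line strips against randomly chosen
# reference strips recovers the shear v along the scan axis, and the
# motion component orthogonal to the vessel is |w1| = |v| sin(theta).

#' Extract the shear (eye-motion) trace from a space-time image
#'
#' Randomly selects `n_refs` reference strips of `strip_lines` lines; each
#' produces a candidate trace by 1-d zero-mean normalized cross-correlation
#' of every strip's spatial profile against the reference profile.
#' Candidate points that jump more than `jump_gate` px from the previous
#' valid point (on the integer-precision trace) are excluded as false
#' positives. Candidates are aligned by subtracting their means and merged
#' point-wise by the median. Points where fewer than half the candidates
#' are valid are invalid; if more than half of the final trace is invalid
#' the extraction fails.
#'
#' @param st a [space_time_image()] with at least
#'   `n_refs * strip_lines` lines and a visible vessel band.
#' @param n_refs number of random reference strips (default 20).
#' @param strip_lines lines per strip (default 32; 15 kHz / 32 = 468.75 Hz
#'   effective sampling).
#' @param jump_gate false-positive gate in px (default 10).
#' @param seed integer seed for the reference-strip selection.
#' @param max_lag largest spatial lag searched, px; defaults to a quarter
#'   of the scan width.
#' @param subpixel parabolic sub-pixel refinement of the correlation peak.
#' @return A shear trace: data frame with per-strip `line_center`, `t`,
#'   shear `v_px` and `v_um` along the scan axis, orthogonal component
#'   `w1_um`, `n_candidates` and `valid`; attributes carry `theta`,
#'   `line_rate`, `sample_rate` (strip rate, Hz) and `n_refs`.
#' @export
extract_shear <- function(st, n_refs = 20, strip_lines = 32, jump_gate = 10,
                          seed = 1, max_lag = NULL, subpixel = TRUE) {
  data <- st$data
  n <- nrow(data); W <- ncol(data)
  ns <- n %/% strip_lines
  if (ns < n_refs)
    stop("record must contain at least n_refs strips", call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(4L, W %/% 4L)
  cm <- colMeans(data)
  if (diff(range(cm)) < 0.05)
    stop("no vessel band detected in the column-intensity profile",
         call. = FALSE)
  # strip spatial profiles (mean over the strip's lines)
  grp <- rep(seq_len(ns), each = strip_lines)
  P <- rowsum(data[seq_len(ns * strip_lines), , drop = FALSE], grp) /
    strip_lines
  refs <- with_seed(substream_seed(seed, "ref-strips"),
                    sort(sample.int(ns, n_refs)))
  lags <- -max_lag:max_lag
  cand <- matrix(NA_real_, ns, n_refs)
  for (j in seq_along(refs)) {
    z <- P[refs[j], ]
    nccs <- matrix(-Inf, ns, length(lags))
    for (li in seq_along(lags)) {
      d <- lags[li]
      i1 <- max(1L, 1L + d); i2 <- min(W, W + d)
      if (i2 - i1 < 8L) next
      S <- P[, i1:i2, drop = FALSE]
      zc <- z[(i1 - d):(i2 - d)]
      zc <- zc - mean(zc)
      zss <- sum(zc^2)
      if (zss < 1e-12) next
      L <- i2 - i1 + 1L
      num <- S %*% zc
      den <- sqrt(pmax(rowSums(S^2) - rowSums(S)^2 / L, 0) * zss)
      v <- num / den
      v[!is.finite(v)] <- -Inf
      nccs[, li] <- v
    }
    pk <- max.col(nccs, ties.method = "first")
    tr_int <- lags[pk]
    # jump gate on the integer-precision candidate
    valid <- rep(TRUE, ns)
    lastv <- tr_int[1]
    for (i in 2:ns) {
      if (abs(tr_int[i] - lastv) > jump_gate) valid[i] <- FALSE
      else lastv <- tr_int[i]
    }
    tr <- as.numeric(tr_int)
    if (subpixel) {
      for (i in seq_len(ns)) {
        k <- pk[i]
        if (k > 1 && k < length(lags) && all(is.finite(nccs[i, (k-1):(k+1)])))
          tr[i] <- lags[k] + peak_refine(nccs[i, (k - 1):(k + 1)])
      }
    }
    tr[!valid] <- NA_real_
    cand[, j] <- tr - mean(tr, na.rm = TRUE)  # align to zero mean
  }
  nvalid <- rowSums(is.finite(cand))
  v_px <- apply(cand, 1, median, na.rm = TRUE)
  valid <- nvalid >= n_refs / 2 & is.finite(v_px)
  v_px[!valid] <- NA_real_
  if (mean(!valid) > 0.5)
    stop("shear extraction failed: more than half of the trace is invalid",
         call. = FALSE)
  sample_rate <- st$line_rate / strip_lines
  line_center <- (seq_len(ns) - 0.5) * strip_lines
  v_um <- v_px * st$space_scale
  out <- data.frame(strip = seq_len(ns), line_center = line_center,
                    t = (line_center - 1) / st$line_rate,
                    v_px = v_px, v_um = v_um, w1_um = NA_real_,
                    n_candidates = nvalid, valid = valid)
  attr(out, "theta") <- st$theta
  attr(out, "line_rate") <- st$line_rate
  attr(out, "sample_rate") <- sample_rate
  attr(out, "space_scale") <- st$space_scale
  attr(out, "n_refs") <- n_refs
  project_orthogonal(out)
}

#' Project the shear trace onto the vessel-orthogonal axis
#'
#' Fills `w1_um = v_um * sin(theta)`, the eye-motion component orthogonal
#' to the imaged vessel. Near-parallel geometries (`theta` close to 0)
#' make the projection insensitive and trigger a warning.
#'
#' @param trace shear trace from [extract_shear()] (attribute `theta`), or
#'   any data frame with `v_um` plus an explicit `theta`.
#' @param theta vessel-to-scan angle, degrees; default from the trace.
#' @return the trace with `w1_um` filled.
#' @export
project_orthogonal <- function(trace, theta = NULL) {
  if (is.null(theta)) theta <- attr(trace, "theta")
  if (is.null(theta)) stop("`theta` is required", call. = FALSE)
  if (theta < 10)
    warning("theta < 10 deg: orthogonal projection is poorly conditioned")
  trace$w1_um <- trace$v_um * sin(theta * pi / 180)
  trace
}

# Linear interpolation across invalid samples (ends held).
interp_na <- function(x) {
  ok <- is.finite(x)
  if (all(ok)) return(x)
  if (!any(ok)) return(rep(0, length(x)))
  approx(which(ok), x[ok], xout = seq_along(x), rule = 2)$y
}

#' Zero-phase high-pass filter
#'
#' Butterworth high-pass applied forward and backward
#' (zero phase); invalid samples are linearly interpolated first. Removes
#' DC and sub-cutoff drift, isolating the tremor band (cutoff default
#' 30 Hz).
#'
#' @param x numeric time series.
#' @param fs sample rate, Hz (must exceed `2 * cutoff`).
#' @param cutoff high-pass corner, Hz.
#' @param order Butterworth order.
#' @return filtered series, same length.
#' @export
highpass <- function(x, fs, cutoff = 30, order = 3) {
  if (fs <= 2 * cutoff)
    stop("sample rate must exceed twice the cutoff", call. = FALSE)
  x <- interp_na(x)
  if (sd(x) == 0) return(rep(0, length(x)))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

#' Welch power spectrum of a motion trace
#'
#' Splits the (NA-interpolated, detrended) series into Hann-windowed
#' segments with 50% overlap and averages their periodograms.
#'
#' @param x numeric time series (>= 64 samples).
#' @param fs sample rate, Hz.
#' @param segment segment length in samples (default `min(1024, n)`).
#' @return An object of class `spectral_density`: data frame fields
#'   `freq` (Hz, 0..fs/2) and `power`, with `fs` and `segment` attributes.
#' @export
motion_spectrum <- function(x, fs, segment = NULL) {
  x <- interp_na(x)
  n <- length(x)
  if (n < 64) stop("series too short for a spectrum", call. = FALSE)
  if (is.null(segment)) segment <- min(1024L, n)
  segment <- min(segment, n)
  x <- x - mean(x)
  step <- max(1L, segment %/% 2L)
  starts <- seq(1L, n - segment + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1))
  wss <- sum(win^2)
  nf <- segment %/% 2L + 1L
  pxx <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment - 1L)]
    X <- fft((seg - mean(seg)) * win)
    p <- Mod(X[seq_len(nf)])^2 / (wss * fs)
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    pxx <- pxx + p
  }
  pxx <- pxx / length(starts)
  out <- data.frame(freq = (seq_len(nf) - 1) * fs / segment, power = pxx)
  attr(out, "fs") <- fs
  attr(out, "segment") <- segment
  class(out) <- c("spectral_density", class(out))
  out
}

#' Find prominent spectral peaks
#'
#' Local maxima of the power spectrum within `c(fmin, fmax)` whose power
#' exceeds `prominence` times the median power of that range, sorted by
#' power. Peak frequencies are refined by parabolic interpolation of the
#' three bins around each maximum, so they are not quantized to the
#' spectral grid.
#'
#' @param spec a `spectral_density` from [motion_spectrum()].
#' @param fmin,fmax frequency range searched, Hz.
#' @param prominence multiple of the in-range median power required.
#' @return data frame of `freq` and `power`, strongest first.
#' @export
find_spectral_peaks <- function(spec, fmin = 0.5, fmax = Inf,
                                prominence = 5) {
  f <- spec$freq; p <- spec$power
  sel <- which(f >= fmin & f <= fmax)
  sel <- sel[sel > 1 & sel < length(f)]
  if (!length(sel)) return(data.frame(freq = numeric(), power = numeric()))
  is_max <- p[sel] > p[sel - 1] & p[sel] >= p[sel + 1]
  floor_p <- prominence * median(p[sel])
  k <- sel[is_max & p[sel] > floor_p]
  k <- k[order(p[k], decreasing = TRUE)]
  df <- if (length(f) > 1) f[2] - f[1] else 0
  freq <- vapply(k, function(i)
    f[i] + df * peak_refine(p[(i - 1):(i + 1)]), numeric(1))
  data.frame(freq = freq, power = p[k])
}

#' Band power of a spectrum
#' @param spec a `spectral_density`.
#' @param lo,hi band edges, Hz.
#' @return mean power within the band.
#' @export
band_power <- function(spec, lo, hi) {
  sel <- spec$freq >= lo & spec$freq <= hi
  if (!any(sel)) return(NA_real_)
  mean(spec$power[sel])
}

#' Summary statistics of a tremor trace
#'
#' Amplitude is the rectified mean of the high-passed orthogonal trace
#' times pi/2 (the rectified-mean to sinusoid-amplitude identity
#' `mean|A sin| = 2A/pi`); alternatives are RMS x sqrt(2) and half the
#' peak-to-peak range. The velocity series is the first difference times
#' the sample rate.
#'
#' @param trace shear trace from [extract_shear()], or a numeric `w1`
#'   vector (then `fs` is required).
#' @param fs sample rate, Hz (from the trace attribute when missing).
#' @param cutoff high-pass corner isolating the tremor band, Hz.
#' @param method amplitude definition: `"rectified_mean"`, `"rms"` or
#'   `"p2p"`.
#' @param scale a [scale_model()] for the arc-minute conversion.
#' @return list with `amplitude_um`, `amplitude_arcmin`,
#'   `velocity_rms_um_s` and the filtered trace.
#' @export
tremor_stats <- function(trace, fs = NULL, cutoff = 30,
                         method = c("rectified_mean", "rms", "p2p"),
                         scale = scale_model()) {
  method <- match.arg(method)
  if (is.data.frame(trace)) {
    if (is.null(fs)) fs <- attr(trace, "sample_rate")
    x <- trace$w1_um
  } else x <- as.numeric(trace)
  if (is.null(fs)) stop("`fs` is required", call. = FALSE)
  hp <- highpass(x, fs, cutoff)
  amp <- switch(method,
                rectified_mean = mean(abs(hp)) * pi / 2,
                rms = sd(hp) * sqrt(2),
                p2p = diff(range(hp)) / 2)
  vel <- diff(hp) * fs
  list(amplitude_um = amp,
       amplitude_arcmin = um_to_arcmin(amp, scale),
       velocity_rms_um_s = sqrt(mean(vel^2)),
       filtered = hp, fs = fs, method = method)
}
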