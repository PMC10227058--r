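# Single-cell blood velocimetry from space-time images via the Radon
# transform, vessel diameter from motion contrast, flow computation and
# the flow-diameter power-law model.
#
# Blood cells appear as diagonal streaks in the space-time image; the
# dominant streak angle is found by rotating each region of interest and
# maximizing the standard deviation of the 1-d intensity projection, and
# maps to cell velocity through the px and line scales.

#' Radon velocimetry configuration
#'
#' @param roi_time ROI length in scan lines (default 128; with 50% overlap
#'   this gives several velocity estimates per cardiac cycle at awake
#'   heart rates).
#' @param roi_overlap fractional overlap of consecutive ROIs in \[0, 1).
#' @param angle_step_coarse,angle_step_fine coarse and fine angle steps,
#'   degrees (1 deg pass then 0.25 deg around the maximum).
#' @param velocity_bandwidth measurable speed range, mm/s (default
#'   `c(0.03, 1275)`); estimates outside it are flagged, not clipped.
#' @param quality_floor minimum peak z-score of the projection-STD
#'   profile (peak minus median in robust-SD units, maximized over
#'   scales) for a valid ROI; pure noise stays below ~2.5.
#' @return An object of class `radon_config`.
#' @export
radon_config <- function(roi_time = 128, roi_overlap = 0.5,
                         angle_step_coarse = 1, angle_step_fine = 0.25,
                         velocity_bandwidth = c(0.03, 1275),
                         quality_floor = 3.5) {
  if (roi_overlap < 0 || roi_overlap >= 1)
    stop("`roi_overlap` must be in [0, 1)", call. = FALSE)
  structure(list(roi_time = roi_time, roi_overlap = roi_overlap,
                 angle_step_coarse = angle_step_coarse,
                 angle_step_fine = angle_step_fine,
                 velocity_bandwidth = velocity_bandwidth,
                 quality_floor = quality_floor),
            class = "radon_config")
}

# Block-average a matrix by integer factors (bt rows, bs cols); trailing
# remainder rows/cols are dropped.
block_bin <- function(m, bt = 1L, bs = 1L) {
  if (bt > 1L) {
    nr <- nrow(m) %/% bt
    m <- rowsum(m[seq_len(nr * bt), , drop = FALSE],
                rep(seq_len(nr), each = bt)) / bt
  }
  if (bs > 1L) {
    nc <- ncol(m) %/% bs
    m <- t(rowsum(t(m[, seq_len(nc * bs), drop = FALSE]),
                  rep(seq_len(nc), each = bs)) / bs)
  }
  m
}

# Projection-STD profile over candidate streak angles (degrees from the
# time/row axis; tan(angle) = px per line). Pixels inside the inscribed
# ellipse are binned along the axis orthogonal to the streak direction and
# the SD of bin means is returned per angle.
radon_angle_scan <- function(roi, angles_deg) {
  H <- nrow(roi); W <- ncol(roi)
  ry <- (seq_len(H) - (H + 1) / 2)
  rx <- (seq_len(W) - (W + 1) / 2)
  Y <- matrix(ry, H, W); X <- matrix(rx, H, W, byrow = TRUE)
  inside <- (Y / (H / 2))^2 + (X / (W / 2))^2 <= 1
  yv <- Y[inside]; xv <- X[inside]; iv <- roi[inside]
  iv <- iv - mean(iv)
  out <- numeric(length(angles_deg))
  for (k in seq_along(angles_deg)) {
    ps <- angles_deg[k] * pi / 180
    tt <- -sin(ps) * yv + cos(ps) * xv
    b <- round(tt - min(tt)) + 1L
    cnt <- tabulate(b)
    s <- rowsum(iv, b)
    keep <- cnt >= max(3, 0.25 * max(cnt))
    mu <- s[keep] / cnt[keep]
    out[k] <- if (length(mu) > 2) sd(mu) else 0
  }
  out
}

#' Dominant streak angle and cell velocity of one ROI
#'
#' The static per-column profile (vessel walls, which would dominate the
#' vertical projection) is removed first, then a two-stage search: a
#' coarse angle pass over automatic time/space block-binnings (which bring
#' the streak slope near 1 px/px so a fixed angle grid can capture it),
#' followed by a multiplicative slope sweep at the most slope-selective
#' scale -- a slope mismatch `eps` smears each streak over
#' `extent * sin(angle) * eps / bs` projection bins, so the finest spatial
#' sampling resolves the slope best once the streak angle is steep.
#' Velocity is
#' `tan(angle) * space_scale * line_rate` (slope in px/line times the
#' scales), corrected for an oblique scan by dividing by
#' `cos(flow_angle)`, the angle between the flow direction and the scan
#' axis. Quality is the peak z-score of the projection-STD profile
#' (peak minus median, in robust-SD units, maximized over scales); ROIs
#' without streaks fall below the floor and are flagged invalid.
#'
#' @param roi matrix patch of a space-time image (lines x space).
#' @param space_scale um per px; `line_rate` lines per second.
#' @param cfg a [radon_config()].
#' @param flow_angle angle between flow direction and scan axis, degrees.
#' @return list with `angle_deg` (from the time axis, native px units),
#'   `velocity_mm_s` (signed), `quality`, `valid` and
#'   `within_bandwidth`.
#' @export
radon_velocity <- function(roi, space_scale = 1, line_rate = 15000,
                           cfg = radon_config(), flow_angle = 0) {
  stopifnot(nrow(roi) >= 8, ncol(roi) >= 8)
  # Remove time-invariant structure (vessel walls project as columns and
  # would dominate the 0-degree projection); the per-column median is
  # robust to the streaks themselves passing through.
  roi <- sweep(roi, 2L, apply(roi, 2L, median))
  scales <- list(c(1L, 1L))
  bt <- 4L
  # time-binned scans need enough remaining rows for a stable projection
  # STD profile (the bin count at steep angles is the row count)
  while (nrow(roi) %/% bt >= 32L) {
    scales[[length(scales) + 1L]] <- c(bt, 1L); bt <- bt * 4L
  }
  bs <- 4L
  while (ncol(roi) %/% bs >= 8L) {
    scales[[length(scales) + 1L]] <- c(1L, bs); bs <- bs * 4L
  }
  coarse <- seq(-88, 88, by = max(cfg$angle_step_coarse, 2))
  cand <- lapply(scales, function(sc) {
    m <- block_bin(roi, sc[1], sc[2])
    stds <- radon_angle_scan(m, coarse)
    med <- median(stds)
    list(contrast = (max(stds) - med) / max(med, 1e-12),
         z = (max(stds) - med) / max(1.4826 * mad(stds), 1e-12),
         sc = sc, m = m, ang = coarse[which.max(stds)])
  })
  # validity asks whether coherent directional structure exists at any
  # scale; the angle is then read off the best-conditioned scale because
  # relative slope error goes as d(angle) / |sin(2 angle)|
  zs <- vapply(cand, `[[`, numeric(1), "z")
  quality <- max(zs)
  qs <- vapply(cand, `[[`, numeric(1), "contrast")
  ok <- which(qs >= 0.35)
  best <- if (length(ok)) {
    cond <- vapply(cand[ok], function(b) abs(sin(2 * b$ang * pi / 180)),
                   numeric(1))
    cand[[ok[which.max(cond)]]]
  } else cand[[which.max(zs)]]
  # coarse estimate of the native slope (px per line); binning time by bt
  # multiplies the apparent slope by bt, binning space by bs divides it
  s0 <- tan(best$ang * pi / 180) * best$sc[2] / best$sc[1]
  if (abs(s0) < 1e-8) {
    # degenerate near-zero slope: refine in angle at the coarse scale
    fine <- seq(best$ang - 2, best$ang + 2, by = cfg$angle_step_fine)
    stds <- radon_angle_scan(best$m, fine)
    k <- which.max(stds)
    ang <- fine[k]
    if (k > 1 && k < length(stds))
      ang <- fine[k] + peak_refine(stds[(k - 1):(k + 1)]) *
        cfg$angle_step_fine
    slope <- tan(ang * pi / 180) * best$sc[2] / best$sc[1]
  } else {
    # refine in slope space at the most slope-selective scale: a slope
    # mismatch eps smears each streak over extent * sin(psi) * eps / bs
    # projection bins, so selectivity is sin(psi) / bs and the finest
    # spatial sampling resolves the slope best once psi is steep
    sel <- vapply(cand, function(b) {
      psi <- atan(abs(s0) * b$sc[1] / b$sc[2])
      sin(psi) / b$sc[2]
    }, numeric(1))
    keep <- which(sel >= 0.5 * max(sel))
    ref <- cand[[keep[which.min(vapply(cand[keep],
                                       function(b) prod(b$sc), numeric(1)))]]]
    ratio <- exp(seq(log(0.75), log(1 / 0.75), length.out = 41L))
    s_mag <- abs(s0)
    for (it in 1:5) {
      sb <- sign(s0) * s_mag * ratio * ref$sc[1] / ref$sc[2]
      fine <- atan(sb) * 180 / pi
      stds <- radon_angle_scan(ref$m, fine)
      k <- which.max(stds)
      if (k > 1L && k < length(stds)) break
      s_mag <- s_mag * ratio[k]   # peak at the window edge: recenter
    }
    lr_hat <- log(ratio[k])
    if (k > 1L && k < length(stds))
      lr_hat <- lr_hat + peak_refine(stds[(k - 1):(k + 1)]) *
        (log(ratio[2]) - log(ratio[1]))
    slope <- sign(s0) * s_mag * exp(lr_hat)
    ang <- atan(slope * best$sc[1] / best$sc[2]) * 180 / pi
  }
  vel <- slope * space_scale * line_rate / 1000 / cos(flow_angle * pi / 180)
  bw <- cfg$velocity_bandwidth
  list(angle_deg = atan(slope) * 180 / pi, velocity_mm_s = vel,
       quality = quality, valid = quality >= cfg$quality_floor,
       within_bandwidth = abs(vel) >= bw[1] & abs(vel) <= bw[2],
       bin = best$sc)
}

#' Velocity time course over sliding ROIs
#'
#' Splits the space-time image into overlapping ROIs
#' (`floor((T - roi)/stride) + 1` of them) and runs [radon_velocity()] on
#' each. Invalid ROIs are interpolated in `velocity_interp` for display
#' but excluded from statistics.
#'
#' @param st a [space_time_image()] long enough for >= 8 ROIs.
#' @param cfg a [radon_config()].
#' @param flow_angle see [radon_velocity()].
#' @return An object of class `cell_velocity_series`: data frame with
#'   `center_t` (s), `angle_deg`, `velocity_mm_s`, `quality`, `valid`,
#'   `within_bandwidth`, `velocity_interp`; sample interval in the
#'   `stride_s` attribute.
#' @export
velocity_timecourse <- function(st, cfg = radon_config(), flow_angle = 0) {
  n <- nrow(st$data)
  stride <- max(1L, round(cfg$roi_time * (1 - cfg$roi_overlap)))
  nroi <- (n - cfg$roi_time) %/% stride + 1L
  if (nroi < 8) stop("record too short for 8 ROIs", call. = FALSE)
  out <- data.frame(roi = seq_len(nroi), center_t = NA_real_,
                    angle_deg = NA_real_, velocity_mm_s = NA_real_,
                    quality = NA_real_, valid = FALSE,
                    within_bandwidth = NA)
  for (i in seq_len(nroi)) {
    r0 <- (i - 1L) * stride + 1L
    roi <- st$data[r0:(r0 + cfg$roi_time - 1L), , drop = FALSE]
    rv <- radon_velocity(roi, st$space_scale, st$line_rate, cfg, flow_angle)
    out$center_t[i] <- (r0 + cfg$roi_time / 2 - 1) / st$line_rate
    out$angle_deg[i] <- rv$angle_deg
    out$velocity_mm_s[i] <- rv$velocity_mm_s
    out$quality[i] <- rv$quality
    out$valid[i] <- rv$valid
    out$within_bandwidth[i] <- rv$within_bandwidth
  }
  vi <- out$velocity_mm_s
  vi[!out$valid] <- NA_real_
  out$velocity_interp <- interp_na(vi)
  attr(out, "stride_s") <- stride / st$line_rate
  class(out) <- c("cell_velocity_series", class(out))
  out
}

#' Fundamental pulse frequency of a velocity series
#'
#' Spectral peak of the (valid, interpolated) velocity series within
#' `c(fmin, fmax)` Hz, reported in Hz and per-minute (2 Hz = 120 per
#' minute). When no peak stands above the prominence floor the rate is
#' "not detected".
#'
#' @param series a `cell_velocity_series` from [velocity_timecourse()].
#' @param fmin,fmax search band, Hz (default 1-20).
#' @param prominence peak prominence floor (multiple of median in-band
#'   power).
#' @return list with `detected`, `freq_hz`, `per_minute`.
#' @export
heart_rate <- function(series, fmin = 1, fmax = 20, prominence = 5) {
  fs <- 1 / attr(series, "stride_s")
  x <- series$velocity_interp
  if (sum(series$valid) < 8 || sd(x) == 0)
    return(list(detected = FALSE, freq_hz = NA_real_,
                per_minute = NA_real_))
  spec <- motion_spectrum(x - mean(x), fs,
                          segment = min(length(x), 512L))
  pk <- find_spectral_peaks(spec, fmin, min(fmax, fs / 2), prominence)
  if (!nrow(pk))
    return(list(detected = FALSE, freq_hz = NA_real_,
                per_minute = NA_real_))
  list(detected = TRUE, freq_hz = pk$freq[1],
       per_minute = hz_to_per_minute(pk$freq[1]))
}

#' Convert a frequency in Hz to events per minute
#' @param hz frequency in Hz.
#' @return events per minute (`hz * 60`).
#' @export
hz_to_per_minute <- function(hz) hz * 60

#' Motion-contrast image of a video
#'
#' Per-pixel temporal standard deviation of a (registered) video;
#' perfused vessels light up because moving blood decorrelates the signal.
#'
#' @param video a `video_frames` object or a time x rows x cols array.
#' @return matrix of temporal SDs.
#' @export
motion_contrast <- function(video) {
  arr <- if (inherits(video, "video_frames")) video$frames else video
  apply(arr, c(2, 3), sd)
}

#' Vessel lumen diameter from a motion-contrast profile
#'
#' Takes the profile of the motion-contrast image along a line
#' perpendicular to the vessel, subtracts the background level, and
#' returns the full width at half maximum (linear interpolation of the
#' half-max crossings) times the pixel scale.
#'
#' @param mc motion-contrast matrix from [motion_contrast()].
#' @param row row index of the profile across the vessel (or a numeric
#'   profile vector via `profile`).
#' @param px_scale um per px.
#' @param profile optional explicit profile, overriding `row`.
#' @return diameter in um.
#' @export
vessel_diameter <- function(mc, row = NULL, px_scale = 1, profile = NULL) {
  p <- if (!is.null(profile)) as.numeric(profile) else mc[row, ]
  bg <- quantile(p, 0.1, names = FALSE)
  pk <- max(p)
  if (pk - bg < 1e-6 || pk - bg < 4 * sd(p[p <= quantile(p, 0.5)]))
    stop("no dominant vessel peak in the motion-contrast profile",
         call. = FALSE)
  half <- bg + (pk - bg) / 2
  im <- which.max(p)
  above <- p >= half
  # contiguous above-half run containing the peak must be unique & single
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  main <- runs[starts[runs] <= im & ends[runs] >= im]
  if (length(main) != 1L || length(runs) > 2L)
    stop("profile lacks a single dominant peak", call. = FALSE)
  i1 <- starts[main]; i2 <- ends[main]
  x1 <- if (i1 > 1)
    (i1 - 1) + (half - p[i1 - 1]) / (p[i1] - p[i1 - 1]) else 1
  x2 <- if (i2 < length(p))
    i2 + (p[i2] - half) / (p[i2] - p[i2 + 1]) else length(p)
  (x2 - x1) * px_scale
}

#' Volumetric flow rate from mean velocity and lumen diameter
#'
#' `flow = velocity * pi * (diameter/2)^2` with units converted to
#' uL/min: mm/s x um^2 gives 1000 um^3/s, and 1 um^3 = 1e-9 uL, so the
#' factor is `6e-5` (1 mm/s through a 50 um lumen is 0.1178 uL/min).
#'
#' @param velocity_mm_s mean cell velocity, mm/s (> 0).
#' @param diameter_um lumen diameter, um (> 0).
#' @return flow in uL/min.
#' @export
flow_rate <- function(velocity_mm_s, diameter_um) {
  stopifnot(velocity_mm_s > 0, diameter_um > 0)
  # mm/s * um^2 = 1000 um^3/s = 1e-6 uL/s = 6e-5 uL/min
  velocity_mm_s * pi * (diameter_um / 2)^2 * 6e-5
}

#' Percent reduction of a flow (or any) value from baseline
#' @param baseline baseline value.
#' @param value later value.
#' @return percent reduction, `100 * (1 - value/baseline)`.
#' @export
percent_reduction <- function(baseline, value) 100 * (1 - value / baseline)

#' Fit the flow-diameter power-law model y = a x^b
#'
#' Least-squares fit of `log y = log a + b log x` to per-vessel records.
#'
#' @param records data frame with columns `diameter` (um) and `flow`
#'   (uL/min); at least 3 records with distinct diameters, all positive.
#' @return An object of class `flow_diameter_model`: list with `a`, `b`,
#'   `n`, `sigma_log` (residual SD on the log scale).
#' @export
fit_flow_diameter <- function(records) {
  d <- records$diameter; y <- records$flow
  if (any(d <= 0) || any(y <= 0))
    stop("diameters and flows must be positive", call. = FALSE)
  if (length(unique(d)) < 3)
    stop("need >= 3 records with distinct diameters", call. = FALSE)
  fit <- lm(log(y) ~ log(d))
  structure(list(a = exp(coef(fit)[[1]]), b = coef(fit)[[2]],
                 n = length(d), sigma_log = sd(residuals(fit))),
            class = "flow_diameter_model")
}

#' @export
print.flow_diameter_model <- function(x, ...) {
  cat(sprintf("flow-diameter model: y = %.4g * x^%.3f (n = %d, sd(log) = %.3f)\n",
              x$a, x$b, x$n, x$sigma_log))
  invisible(x)
}

#' Predict flow from the power-law model
#' @param object a `flow_diameter_model`.
#' @param diameter vessel diameters, um.
#' @param ... unused.
#' @return predicted flows, uL/min.
#' @export
predict.flow_diameter_model <- function(object, diameter, ...) {
  object$a * diameter^object$b
}
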