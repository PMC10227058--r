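# Synthetic-data generators with known ground truth.
#
# Every generator is a pure function of (parameters, seed): the RNG state of
# the session is saved and restored, and per-generator streams are derived
# from one master seed, so regeneration is bit-identical.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Named substream: stable small hash of the stream name folded into the
# master seed, kept below 2^31.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  (abs(as.numeric(seed)) * 7919 + h) %% 2147483587 + 1
}

# ---- tremor traces ---------------------------------------------------------

#' Ocular micro-tremor model
#'
#' Parameters of the synthetic fixational eye-motion trace: a band-limited
#' stochastic tremor component (default 30-200 Hz) plus sinusoidal
#' respiratory (2 Hz) and cardiac (9 Hz) components. Amplitudes are in
#' microns of retinal displacement orthogonal to the imaged vessel.
#'
#' @param band_lo,band_hi tremor band edges, Hz.
#' @param rms_amplitude RMS of the band-limited component, um.
#' @param resp_freq,resp_amp respiratory frequency (Hz) and amplitude (um).
#' @param cardiac_freq,cardiac_amp cardiac frequency (Hz) and amplitude (um).
#' @param seed integer master seed.
#' @return An object of class `tremor_model`.
#' @export
tremor_model <- function(band_lo = 30, band_hi = 200, rms_amplitude = 2,
                         resp_freq = 2, resp_amp = 1.5,
                         cardiac_freq = 9, cardiac_amp = 1.0, seed = 1) {
  stopifnot(band_lo < band_hi, rms_amplitude >= 0, resp_amp >= 0,
            cardiac_amp >= 0)
  structure(list(band_lo = band_lo, band_hi = band_hi,
                 rms_amplitude = rms_amplitude,
                 resp_freq = resp_freq, resp_amp = resp_amp,
                 cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
                 seed = seed),
            class = "tremor_model")
}

# Exactly band-limited unit-RMS noise via frequency-domain masking.
gen_bandlimited <- function(n, fs, lo, hi) {
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  X[f < lo | f > hi] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y / s else y
}

#' Generate a synthetic eye-motion trace
#'
#' @param model a [tremor_model()].
#' @param n number of samples.
#' @param fs sample rate, Hz; must exceed `2 * band_hi`.
#' @return numeric vector of displacements in um.
#' @export
gen_tremor_trace <- function(model, n, fs) {
  if (model$band_hi >= fs / 2)
    stop("tremor band exceeds the Nyquist rate", call. = FALSE)
  with_seed(substream_seed(model$seed, "tremor"), {
    t <- (seq_len(n) - 1) / fs
    tr <- numeric(n)
    if (model$rms_amplitude > 0)
      tr <- model$rms_amplitude *
        gen_bandlimited(n, fs, model$band_lo, model$band_hi)
    ph <- runif(2, 0, 2 * pi)
    tr + model$resp_amp * sin(2 * pi * model$resp_freq * t + ph[1]) +
      model$cardiac_amp * sin(2 * pi * model$cardiac_freq * t + ph[2])
  })
}

# ---- pupil-camera scenes ---------------------------------------------------

#' Pupil-camera scene description
#'
#' A low-texture elliptical pupil drifting over a high-texture speckle
#' background (fur/eyelid analogue), with optional whole-frame darkening
#' during blink intervals.
#'
#' @param width,height frame size, px.
#' @param center pupil center at the first frame, `c(x, y)` px.
#' @param drift per-frame center displacement `c(dx, dy)` px/frame, or an
#'   `n x 2` matrix of absolute centers.
#' @param axes ellipse semi-axes `c(a, b)` px, `a >= b`; the default is a
#'   fully dilated mouse pupil (about 2 mm across at the default scale).
#' @param orientation ellipse orientation, degrees.
#' @param blink_intervals blink `(start, end)` intervals in seconds: a
#'   2-column matrix or a list of length-2 vectors.
#' @param mm_per_px physical scale of the pupil camera.
#' @param pupil_level,pupil_noise pupil interior intensity and noise SD.
#' @param seed integer master seed.
#' @return An object of class `pupil_scene`.
#' @export
pupil_scene <- function(width = 320, height = 240,
                        center = c(160, 120), drift = c(0, 0),
                        axes = c(100, 95), orientation = 0,
                        blink_intervals = NULL, mm_per_px = 0.01,
                        pupil_level = 0.12, pupil_noise = 0.02, seed = 1) {
  stopifnot(axes[1] >= axes[2], axes[2] > 0)
  if (2 * axes[1] >= min(width, height))
    stop("pupil larger than the frame", call. = FALSE)
  structure(list(width = width, height = height, center = center,
                 drift = drift, axes = axes, orientation = orientation,
                 blink_intervals = blink_intervals, mm_per_px = mm_per_px,
                 pupil_level = pupil_level, pupil_noise = pupil_noise,
                 seed = seed),
            class = "pupil_scene")
}

in_interval <- function(t, intervals) {
  if (is.null(intervals)) return(rep(FALSE, length(t)))
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(intervals, ncol = 2)
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals)))
    out <- out | (t >= intervals[i, 1] & t < intervals[i, 2])
  out
}

ellipse_mask <- function(h, w, cx, cy, a, b, phi_deg) {
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  ph <- phi_deg * pi / 180
  u <- (X - cx) * cos(ph) + (Y - cy) * sin(ph)
  v <- -(X - cx) * sin(ph) + (Y - cy) * cos(ph)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a pupil-camera video with ground truth
#'
#' @param scene a [pupil_scene()].
#' @param n_frames number of frames.
#' @param frame_rate frames per second (default 8.8, the SLO pupil stream).
#' @return list with `video` ([video_frames()]) and `truth`, a data frame of
#'   per-frame center, semi-axes, orientation and blink flag.
#' @export
gen_pupil_video <- function(scene, n_frames, frame_rate = 8.8) {
  n <- as.integer(n_frames)
  t <- (seq_len(n) - 1) / frame_rate
  if (is.matrix(scene$drift)) {
    centers <- scene$drift
    if (nrow(centers) != n) stop("center trace length mismatch", call. = FALSE)
  } else {
    centers <- cbind(scene$center[1] + (seq_len(n) - 1) * scene$drift[1],
                     scene$center[2] + (seq_len(n) - 1) * scene$drift[2])
  }
  a <- scene$axes[1]; b <- scene$axes[2]
  if (any(centers[, 1] - a < 1 | centers[, 1] + a > scene$width |
          centers[, 2] - a < 1 | centers[, 2] + a > scene$height))
    stop("pupil leaves the frame", call. = FALSE)
  blink <- in_interval(t, scene$blink_intervals)
  frames <- vector("list", n)
  with_seed(substream_seed(scene$seed, "pupil"), {
    bg <- matrix(as.numeric(runif(scene$height * scene$width) > 0.5),
                 scene$height, scene$width)
    for (k in seq_len(n)) {
      f <- bg
      m <- ellipse_mask(scene$height, scene$width, centers[k, 1],
                        centers[k, 2], a, b, scene$orientation)
      f[m] <- scene$pupil_level + rnorm(sum(m), 0, scene$pupil_noise)
      if (blink[k]) f <- f * 0.25
      f[f < 0] <- 0; f[f > 1] <- 1
      frames[[k]] <- f
    }
  })
  video <- video_frames(frames, frame_rate = frame_rate,
                        pixel_scale = scene$mm_per_px, pixel_units = "mm/px")
  truth <- data.frame(frame = seq_len(n), t = t,
                      cx = centers[, 1], cy = centers[, 2],
                      a = a, b = b, orientation = scene$orientation,
                      blink = blink)
  list(video = video, truth = truth)
}

# ---- retina-like texture and SLO video -------------------------------------

#' Generate a retina-like texture
#'
#' Smoothed random field plus dark curvilinear vessel-like paths, so that
#' correlation trackers see realistic features (vessel junctions, local
#' contrast) without any real data.
#'
#' @param height,width texture size, px.
#' @param n_vessels number of dark curvilinear paths.
#' @param contrast vessel darkening depth on the \[0,1\] scale.
#' @param seed integer seed.
#' @return numeric matrix in \[0,1\].
#' @export
gen_retina_texture <- function(height = 256, width = 256, n_vessels = 6,
                               contrast = 0.5, seed = 1) {
  with_seed(substream_seed(seed, "retina-texture"), {
    base <- matrix(runif(height * width), height, width)
    base <- presmooth(base, sigma = 2.5)
    base <- normalize01(base) * 0.6 + 0.3
    for (v in seq_len(n_vessels)) {
      len <- round(1.5 * max(height, width))
      ang <- runif(1, 0, 2 * pi)
      x <- runif(1, 1, width); y <- runif(1, 1, height)
      wobble <- cumsum(rnorm(len, 0, 0.08))
      xs <- x + cumsum(cos(ang + wobble))
      ys <- y + cumsum(sin(ang + wobble))
      wd <- sample(1:2, 1)
      for (ox in -wd:wd) for (oy in -wd:wd) {
        xi <- round(xs) + ox; yi <- round(ys) + oy
        keep <- xi >= 1 & xi <= width & yi >= 1 & yi <= height
        base[cbind(yi[keep], xi[keep])] <-
          base[cbind(yi[keep], xi[keep])] - contrast / (1 + ox^2 + oy^2)
      }
    }
    base[base < 0.02] <- 0.02; base[base > 1] <- 1
    base
  })
}

#' Generate an SLO retinal video translated by a known gaze trace
#'
#' Each frame is a fixed retina-like texture translated (sub-pixel,
#' bilinear) by the per-frame gaze offset; blink frames are globally scaled
#' to 40% of their intensity so they fall below the 60%-of-video-mean blink
#' rule.
#'
#' @param motion `n x 2` matrix of gaze offsets (dx, dy) in degrees;
#'   positive right/down.
#' @param frame_rate frames per second.
#' @param deg_per_px angular pixel scale.
#' @param height,width frame size, px.
#' @param blink_frames integer indices of blink frames.
#' @param noise_sd additive Gaussian noise SD.
#' @param base optional texture matrix (must exceed the frame by the motion
#'   margin); generated when `NULL`.
#' @param seed integer master seed.
#' @return list with `video` and `truth` (data frame of offsets in degrees
#'   and px plus blink flags).
#' @export
gen_slo_video <- function(motion, frame_rate = 8.8, deg_per_px = 0.1,
                          height = 160, width = 160, blink_frames = integer(),
                          noise_sd = 0.02, base = NULL, seed = 1) {
  motion <- matrix(motion, ncol = 2)
  n <- nrow(motion)
  mpx <- motion / deg_per_px
  margin <- ceiling(max(abs(mpx), 0)) + 2L
  if (max(abs(mpx[, 1])) > 0.75 * width || max(abs(mpx[, 2])) > 0.75 * height)
    stop("motion violates the 25% overlap requirement", call. = FALSE)
  if (is.null(base))
    base <- gen_retina_texture(height + 2L * margin, width + 2L * margin,
                               seed = seed)
  if (nrow(base) < height + 2 * margin || ncol(base) < width + 2 * margin)
    stop("base texture too small for the requested motion", call. = FALSE)
  frames <- vector("list", n)
  blink <- seq_len(n) %in% blink_frames
  with_seed(substream_seed(seed, "slo-noise"), {
    for (k in seq_len(n)) {
      f <- bilinear_grid(base,
                         seq_len(height) + margin - mpx[k, 2],
                         seq_len(width) + margin - mpx[k, 1])
      if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
      if (blink[k]) f <- f * 0.4
      f[f < 0] <- 0; f[f > 1] <- 1
      frames[[k]] <- f
    }
  })
  video <- video_frames(frames, frame_rate = frame_rate,
                        pixel_scale = deg_per_px, pixel_units = "deg/px")
  truth <- data.frame(frame = seq_len(n),
                      t = (seq_len(n) - 1) / frame_rate,
                      dx_deg = motion[, 1], dy_deg = motion[, 2],
                      dx_px = mpx[, 1], dy_px = mpx[, 2], blink = blink)
  list(video = video, truth = truth)
}

# ---- line-scan space-time images -------------------------------------------

#' Blood-cell streak model for line-scan images
#'
#' @param velocities cell velocities in mm/s (recycled over streaks); must
#'   lie within the (0.03, 1275) mm/s measurement bandwidth.
#' @param density streaks per millisecond (ignored when `n_streaks` given).
#' @param n_streaks optional explicit streak count.
#' @param contrast streak brightness added inside the vessel band.
#' @param sigma_px streak cross-section SD, px.
#' @param max_streak_lines cap on the rendered streak duration in lines
#'   (bounds slow/stationary cells).
#' @param seed integer seed.
#' @return An object of class `streak_model`.
#' @export
streak_model <- function(velocities = 10, density = 0.5, n_streaks = NULL,
                         contrast = 0.35, sigma_px = 1.2,
                         max_streak_lines = 2000, seed = 1) {
  if (any(abs(velocities) <= 0.03 | abs(velocities) >= 1275))
    stop("velocities must lie within the (0.03, 1275) mm/s bandwidth",
         call. = FALSE)
  structure(list(velocities = velocities, density = density,
                 n_streaks = n_streaks, contrast = contrast,
                 sigma_px = sigma_px, max_streak_lines = max_streak_lines,
                 seed = seed),
            class = "streak_model")
}

#' Generate a line-scan space-time image with ground truth
#'
#' Renders a vessel band whose position along the scan axis is sheared
#' line-by-line by `w1(t) / sin(theta)` -- so the orthogonal motion
#' component `w1` is the truth trace in the units the analysis reports --
#' plus diagonal blood-cell streaks whose along-scan slope in px/line is
#' `velocity / (space_scale * line_rate)` (velocities in mm/s, scale in
#' um/px).
#'
#' @param duration record length, seconds (`duration * line_rate >= 2048`).
#' @param tremor a [tremor_model()], an explicit numeric `w1` trace in um
#'   (one value per line), or `NULL` for a motion-free record.
#' @param streaks a [streak_model()] or `NULL` for no cells.
#' @param line_rate scan rate, Hz.
#' @param space_scale um per px along the scan axis.
#' @param theta vessel-to-scan angle, degrees.
#' @param width_px samples per line.
#' @param band_center,band_width vessel band center and width, px.
#' @param band_depth vessel darkening depth; `edge_width` ramp width px.
#' @param noise_sd additive noise SD.
#' @param seed integer master seed.
#' @return list with `st` (a [space_time_image()]), `truth` (per-line `t`,
#'   `w1_um`, `shear_px`) and `streak_truth` (per-streak start line and
#'   velocity in mm/s).
#' @export
gen_linescan <- function(duration, tremor = NULL, streaks = NULL,
                         line_rate = 15000, space_scale = 1, theta = 90,
                         width_px = 160, band_center = NULL, band_width = 60,
                         band_depth = 0.55, edge_width = 4, noise_sd = 0.02,
                         seed = 1) {
  n <- round(duration * line_rate)
  if (n < 2048) stop("record must span at least 2048 lines", call. = FALSE)
  if (is.null(band_center)) band_center <- (width_px + 1) / 2
  if (is.null(tremor)) {
    w1 <- numeric(n)
  } else if (inherits(tremor, "tremor_model")) {
    w1 <- gen_tremor_trace(tremor, n, line_rate)
  } else {
    w1 <- as.numeric(tremor)
    if (length(w1) != n) stop("tremor trace length must equal the line count",
                              call. = FALSE)
  }
  shear_px <- w1 / sin(theta * pi / 180) / space_scale
  centers <- band_center + shear_px
  hw <- band_width / 2
  if (any(centers - hw < 1 + edge_width) ||
      any(centers + hw > width_px - edge_width))
    stop("vessel band leaves the field", call. = FALSE)
  x <- seq_len(width_px)
  D <- abs(outer(centers, x, "-"))
  atten <- band_depth * pmin(pmax((hw - D) / edge_width + 0.5, 0), 1)
  img <- 0.78 - atten
  streak_truth <- NULL
  if (!is.null(streaks)) {
    with_seed(substream_seed(streaks$seed, "streaks"), {
      ns <- if (!is.null(streaks$n_streaks)) streaks$n_streaks
            else max(1L, round(streaks$density * duration * 1000))
      vel <- rep_len(streaks$velocities, ns)
      t0 <- sort(runif(ns, 1, n))
      streak_truth <- data.frame(line0 = t0, velocity = vel)
      for (si in seq_len(ns)) {
        v_px <- vel[si] * 1000 / (space_scale * line_rate)  # px per line
        x_enter <- if (v_px >= 0) band_center - hw else band_center + hw
        dur <- if (abs(v_px) > 1e-9) band_width / abs(v_px) else Inf
        dur <- min(dur, streaks$max_streak_lines, n - t0[si])
        dt <- min(0.5, 0.5 / max(abs(v_px), 1e-9))
        dt <- max(dt, dur / 2e5)  # bound samples per streak
        ts <- seq(0, dur, by = dt)
        ls <- t0[si] + ts
        ok <- ls >= 1 & ls <= n - 1
        ts <- ts[ok]; ls <- ls[ok]
        if (!length(ts)) next
        l0 <- floor(ls); fl <- ls - l0
        xs <- x_enter + v_px * ts + shear_px[l0]
        x0 <- floor(xs); fx <- xs - x0
        # per-(line, pixel) deposit ~ contrast regardless of speed: samples
        # per pixel scale as 1 / (max(|v_px|, 1) * dt), so weight by the
        # inverse to keep streak contrast constant along the trail
        w <- streaks$contrast * dt * max(abs(v_px), 1)
        # bilinear deposit in line and space: rounding the line index would
        # erase sub-line timing and bias the apparent slope of cells that
        # cross the band in less than one scan line
        idx <- c(l0 + (x0 - 1) * n, l0 + x0 * n,
                 l0 + 1 + (x0 - 1) * n, l0 + 1 + x0 * n)
        wts <- c(w * (1 - fl) * (1 - fx), w * (1 - fl) * fx,
                 w * fl * (1 - fx), w * fl * fx)
        ok2 <- rep(x0 >= 1 & x0 < width_px, 4)
        idx <- idx[ok2]; wts <- wts[ok2]
        if (!length(idx)) next
        add <- rowsum(wts, idx)
        ii <- as.integer(rownames(add))
        img[ii] <- img[ii] + add[, 1]
      }
    })
  }
  with_seed(substream_seed(seed, "linescan-noise"), {
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  })
  img[img < 0] <- 0; img[img > 1] <- 1
  st <- space_time_image(img, line_rate = line_rate,
                         space_scale = space_scale, theta = theta)
  truth <- data.frame(line = seq_len(n), t = (seq_len(n) - 1) / line_rate,
                      w1_um = w1, shear_px = shear_px)
  list(st = st, truth = truth, streak_truth = streak_truth)
}

#' Generate an AOSLO-like raster video with intra-frame shear
#'
#' Each frame scans a fixed retina-like texture line by line; the
#' horizontal sampling position of every scan line is displaced by a
#' band-limited shear trace evaluated at that line's acquisition time
#' (plus an optional per-frame rigid offset), emulating the intra-frame
#' wobble fast eye motion imposes on scanned imagers. The per-line shear
#' is returned as ground truth.
#'
#' @param n_frames frames to render.
#' @param height,width frame size px (`height` scan lines per frame).
#' @param shear_amp_px RMS of the band-limited intra-frame shear, px.
#' @param band tremor band of the shear, Hz, at `line_rate`.
#' @param line_rate lines per second.
#' @param frame_offsets optional `n x 2` per-frame rigid (dx, dy) px.
#' @param noise_sd additive noise SD.
#' @param seed integer master seed.
#' @return list with `video`, `shear_px` (matrix n_frames x height: truth
#'   per line) and `frame_offsets`.
#' @export
gen_aoslo_video <- function(n_frames, height = 128, width = 128,
                            shear_amp_px = 4, band = c(30, 200),
                            line_rate = 15000, frame_offsets = NULL,
                            noise_sd = 0.01, seed = 1) {
  margin <- ceiling(shear_amp_px * 4 +
                      if (is.null(frame_offsets)) 0
                      else max(abs(frame_offsets))) + 2L
  base <- gen_retina_texture(height + 2L * margin, width + 2L * margin,
                             seed = substream_seed(seed, "aoslo-base"))
  if (is.null(frame_offsets)) frame_offsets <- matrix(0, n_frames, 2)
  shear <- matrix(0, n_frames, height)
  if (shear_amp_px > 0) {
    with_seed(substream_seed(seed, "aoslo-shear"), {
      tr <- shear_amp_px *
        gen_bandlimited(n_frames * height, line_rate, band[1], band[2])
    })
    shear <- matrix(tr, n_frames, height, byrow = TRUE)
  }
  frames <- vector("list", n_frames)
  with_seed(substream_seed(seed, "aoslo-noise"), {
    for (k in seq_len(n_frames)) {
      f <- matrix(0, height, width)
      for (s in seq_len(height)) {
        dx <- shear[k, s] + frame_offsets[k, 1]
        f[s, ] <- bilinear_grid(base,
                                margin + s + frame_offsets[k, 2],
                                seq_len(width) + margin - dx)[1, ]
      }
      if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
      f[f < 0] <- 0; f[f > 1] <- 1
      frames[[k]] <- f
    }
  })
  list(video = video_frames(frames, frame_rate = line_rate / height),
       shear_px = shear, frame_offsets = frame_offsets)
}

# ---- OCT volumes -----------------------------------------------------------

#' Generate a synthetic OCT volume with known boundaries
#'
#' Each B-scan has a dark vitreous above a bright retinal band: the
#' dark-to-bright transition is the ILM, the bright-to-dark transition at
#' the bottom of the band is the OS-RPE boundary, and their separation is
#' the requested total retinal thickness (TRT).
#'
#' @param thickness_map en-face TRT grid in um, `n_bscans x width`.
#' @param axial_scale um per px in depth.
#' @param depth_px A-scan depth in px; must exceed the deepest boundary.
#' @param ilm_base mean ILM depth, um; `ilm_amp` adds a smooth undulation.
#' @param noise multiplicative speckle SD (0 for noiseless).
#' @param en_face_scale degrees per cell `c(per B-scan, per column)`.
#' @param disc_center optic-disc center in en-face degrees `c(x, y)`
#'   relative to the map center.
#' @param seed integer seed.
#' @return list with `volume` (class `oct_volume`: array n_bscans x depth x
#'   width plus scales) and `truth` (`ilm_px`, `osrpe_px` matrices and the
#'   input map).
#' @export
gen_oct_volume <- function(thickness_map, axial_scale = 2, depth_px = 256,
                           ilm_base = 80, ilm_amp = 12, noise = 0.05,
                           en_face_scale = c(0.3, 0.3),
                           disc_center = c(0, 0), seed = 1) {
  thickness_map <- as.matrix(thickness_map)
  nb <- nrow(thickness_map); wd <- ncol(thickness_map)
  xs <- seq_len(wd) / wd
  with_seed(substream_seed(seed, "oct"), {
    ph <- runif(nb, 0, 2 * pi)
    ilm_um <- ilm_base + ilm_amp * sin(outer(ph, 2 * pi * xs, "+"))
    ilm_px <- ilm_um / axial_scale
    osrpe_px <- ilm_px + thickness_map / axial_scale
    if (max(osrpe_px) >= depth_px - 4)
      stop("thickness exceeds the axial extent", call. = FALSE)
    vol <- array(0, c(nb, depth_px, wd))
    r <- seq_len(depth_px)
    for (b in seq_len(nb)) {
      up <- outer(r, ilm_px[b, ], "-")     # >0 below ILM
      dn <- outer(r, osrpe_px[b, ], "-")   # >0 below OS-RPE
      I <- 0.08 + (0.62 - 0.08) * stats::plogis(up / 0.8) +
        (0.12 - 0.62) * stats::plogis(dn / 0.8)
      if (noise > 0) I <- I * (1 + rnorm(length(I), 0, noise))
      I[I < 0] <- 0; I[I > 1] <- 1
      vol[b, , ] <- I
    }
  })
  volume <- structure(
    list(data = vol, axial_scale = axial_scale,
         en_face_scale = en_face_scale, disc_center = disc_center),
    class = "oct_volume")
  list(volume = volume,
       truth = list(ilm_px = ilm_px, osrpe_px = osrpe_px,
                    trt_um = thickness_map))
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("oct_volume: %d B-scans x %d depth x %d width, %g um/px axial\n",
              d[1], d[2], d[3], x$axial_scale))
  invisible(x)
}

# ---- quadrature encoder ----------------------------------------------------

#' Generate quadrature encoder pulse trains for a known speed profile
#'
#' Emulates a counts-per-revolution rotary encoder on a running wheel: the
#' A/B square waves advance through the 4-state Gray sequence at
#' `4 * cpr * speed / circumference` edges per second.
#'
#' @param speed speed profile in m/s, one value per output sample (signed;
#'   negative reverses direction).
#' @param sample_rate acquisition rate, Hz; must be at least 20x the peak
#'   edge rate or the generator refuses (aliasing).
#' @param cpr encoder counts per revolution (default 256).
#' @param wheel_diameter wheel diameter in m (default 0.090).
#' @return list with `A`, `B` (0/1 vectors), `t` (s), and `truth`, the 1 s
#'   binned speed magnitude.
#' @export
gen_quadrature <- function(speed, sample_rate, cpr = 256,
                           wheel_diameter = 0.090) {
  circumference <- pi * wheel_diameter
  max_edge_rate <- 4 * cpr * max(abs(speed)) / circumference
  if (sample_rate < 20 * max_edge_rate)
    stop("sample_rate below 20x the peak edge rate (aliasing)", call. = FALSE)
  dist <- cumsum(speed) / sample_rate          # signed metres
  edges <- floor(dist / circumference * cpr * 4)
  state <- ((edges %% 4) + 4) %% 4             # 0,1,2,3 Gray sequence
  A <- as.integer(state == 1 | state == 2)
  B <- as.integer(state == 2 | state == 3)
  t <- (seq_along(speed) - 1) / sample_rate
  truth <- bin_by_time(t, abs(speed), bin_width = 1, t0 = 0)
  list(A = A, B = B, t = t, sample_rate = sample_rate, cpr = cpr,
       wheel_diameter = wheel_diameter,
       truth = data.frame(t_start = truth$t_start, speed = truth$mean))
}
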