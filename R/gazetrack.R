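# Blink detection and template-based gaze tracking for SLO retinal video.

#' Reference template set for gaze tracking
#'
#' Exactly three templates with well-defined features (optic disc, vessel
#' junctions) selected from one reference frame; positions and sizes come
#' from configuration, mirroring expert selection.
#'
#' @param video a `video_frames` object.
#' @param rects list of three `c(x, y, w, h)` vectors: template top-left
#'   (px, 1-based) and size in the reference frame.
#' @param reference_frame index of the reference frame.
#' @return An object of class `template_set`.
#' @export
template_set <- function(video, rects, reference_frame = 1) {
  if (length(rects) != 3L)
    stop("exactly 3 templates are required", call. = FALSE)
  ref <- get_frame(video, reference_frame)
  tpls <- lapply(rects, function(r) {
    x <- r[1]; y <- r[2]; w <- r[3]; h <- r[4]
    if (x < 1 || y < 1 || x + w - 1 > ncol(ref) || y + h - 1 > nrow(ref))
      stop("template not fully inside the reference frame", call. = FALSE)
    list(patch = ref[y:(y + h - 1), x:(x + w - 1), drop = FALSE],
         x = x, y = y)
  })
  structure(list(templates = tpls, reference_frame = reference_frame),
            class = "template_set")
}

#' Detect blink frames in an SLO video
#'
#' A frame is flagged as a blink when its mean intensity falls below 60% of
#' the average image intensity of the whole video. Contiguous flagged runs
#' are grouped into blink events with start frame and duration. The rule is
#' invariant to global intensity gain.
#'
#' @param video a `video_frames` object (per-video normalized).
#' @param fraction blink threshold as a fraction of the whole-video mean
#'   (default 0.60).
#' @return list with `flags` (logical per frame), `events` (data frame of
#'   start frame, length in frames, start time and duration in seconds)
#'   and the intensity `threshold` used.
#' @export
detect_blinks <- function(video, fraction = 0.60) {
  fm <- apply(video$frames, 1, mean)
  thr <- fraction * mean(fm)
  flags <- fm < thr
  events <- data.frame(start_frame = integer(), n_frames = integer(),
                       start_t = numeric(), duration_s = numeric())
  if (any(flags)) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)
    events <- data.frame(
      start_frame = starts[k], n_frames = r$lengths[k],
      start_t = video$timestamps[starts[k]],
      duration_s = r$lengths[k] / video$frame_rate)
  }
  list(flags = flags, events = events, threshold = thr,
       frame_means = fm)
}

#' Blink duration implied by a frame count
#'
#' Converts a run of blink-flagged frames into a duration at the video
#' frame rate; three frames at 8.8 fps correspond to 340.9 ms.
#'
#' @param n_frames frames in the blink event.
#' @param frame_rate frames per second.
#' @return duration in milliseconds.
#' @export
blink_duration_ms <- function(n_frames, frame_rate = 8.8) {
  n_frames / frame_rate * 1000
}

#' Track retinal gaze position with three reference templates
#'
#' Each template is cross-correlated (zero-mean NCC) against every
#' non-blink frame; the offset of the template with the largest NCC wins
#' and is converted to degrees relative to the reference frame. Frames
#' where all three NCCs fall below `ncc_floor` are invalid, as are blink
#' frames and (optionally) their immediate neighbors.
#'
#' @param video a `video_frames` object with a `deg/px` pixel scale.
#' @param templates a [template_set()].
#' @param ncc_floor minimum winning NCC (default 0.3).
#' @param subpixel parabolic sub-pixel refinement of the peak.
#' @param blinks optional result of [detect_blinks()]; computed when `NULL`.
#' @param invalidate_adjacent also invalidate frames adjacent to blinks.
#' @return gaze trace data frame: per frame `t`, offsets in px and degrees
#'   (positive right/down), winning template, `ncc`, `blink`, `valid`.
#' @export
track_gaze <- function(video, templates, ncc_floor = 0.3, subpixel = TRUE,
                       blinks = NULL, invalidate_adjacent = TRUE) {
  if (is.null(blinks)) blinks <- detect_blinks(video)
  deg_per_px <- video$pixel_scale
  n <- n_frames(video)
  out <- data.frame(frame = seq_len(n), t = video$timestamps,
                    dx_px = NA_real_, dy_px = NA_real_,
                    dx_deg = NA_real_, dy_deg = NA_real_,
                    template = NA_integer_, ncc = NA_real_,
                    blink = blinks$flags, valid = FALSE)
  dead <- blinks$flags
  if (invalidate_adjacent && any(dead)) {
    idx <- which(blinks$flags)
    dead[pmax(idx - 1L, 1L)] <- TRUE
    dead[pmin(idx + 1L, n)] <- TRUE
  }
  for (k in seq_len(n)) {
    if (dead[k]) next
    fr <- get_frame(video, k)
    best <- list(ncc = -Inf)
    for (ti in seq_along(templates$templates)) {
      tp <- templates$templates[[ti]]
      map <- ncc_match(fr, tp$patch)
      pk <- ncc_peak(map, subpixel)
      if (pk$ncc > best$ncc)
        best <- list(ncc = pk$ncc, dx = pk$col - tp$x, dy = pk$row - tp$y,
                     template = ti)
    }
    out$ncc[k] <- best$ncc
    if (best$ncc >= ncc_floor) {
      out$dx_px[k] <- best$dx; out$dy_px[k] <- best$dy
      out$dx_deg[k] <- best$dx * deg_per_px
      out$dy_deg[k] <- best$dy * deg_per_px
      out$template[k] <- best$template
      out$valid[k] <- TRUE
    }
  }
  attr(out, "frame_rate") <- video$frame_rate
  out
}

#' Window-normalize a gaze trace and score positional persistence
#'
#' Within each consecutive window (default 10 s) the offsets of valid
#' samples are re-referenced to the window mean; the fraction of valid
#' samples whose radial offset from the window mean is below `radius_deg`
#' is reported. Windows with no valid samples contribute nothing to the
#' denominator.
#'
#' @param trace gaze trace from [track_gaze()].
#' @param window window length, s (default 10).
#' @param radius_deg persistence radius, degrees (default 5).
#' @return list with `trace` (normalized `dx_deg`/`dy_deg` columns added)
#'   and `fraction_within`, the fraction of valid samples within
#'   `radius_deg` of their window mean.
#' @export
window_normalize <- function(trace, window = 10, radius_deg = 5) {
  if (diff(range(trace$t)) < window)
    stop("trace shorter than one window", call. = FALSE)
  wid <- floor(trace$t / window)
  dxn <- rep(NA_real_, nrow(trace)); dyn <- dxn
  within <- logical(0)
  for (w in unique(wid)) {
    sel <- which(wid == w & trace$valid)
    if (!length(sel)) next
    mx <- mean(trace$dx_deg[sel]); my <- mean(trace$dy_deg[sel])
    dxn[sel] <- trace$dx_deg[sel] - mx
    dyn[sel] <- trace$dy_deg[sel] - my
    within <- c(within, sqrt(dxn[sel]^2 + dyn[sel]^2) < radius_deg)
  }
  trace$dx_norm <- dxn; trace$dy_norm <- dyn
  list(trace = trace,
       fraction_within = if (length(within)) mean(within) else NA_real_)
}

#' Gaze velocity from a gaze trace
#'
#' Centered first difference of the offsets times the frame rate; end
#' points use one-sided differences. Invalid samples propagate `NA`.
#'
#' @param trace gaze trace from [track_gaze()].
#' @param frame_rate frames per second; taken from the trace attribute when
#'   missing.
#' @return data frame with `t` and `speed_deg_s` (magnitude, deg/s).
#' @export
gaze_velocity <- function(trace, frame_rate = NULL) {
  if (is.null(frame_rate)) frame_rate <- attr(trace, "frame_rate")
  x <- ifelse(trace$valid, trace$dx_deg, NA_real_)
  y <- ifelse(trace$valid, trace$dy_deg, NA_real_)
  n <- length(x)
  cd <- function(v) {
    d <- rep(NA_real_, n)
    if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    if (n >= 2) { d[1] <- v[2] - v[1]; d[n] <- v[n] - v[n - 1] }
    d * frame_rate
  }
  data.frame(t = trace$t, speed_deg_s = sqrt(cd(x)^2 + cd(y)^2))
}

#' Correlate gaze velocity with gait speed
#'
#' Both series are averaged into common 1 s bins; the Pearson correlation
#' between the absolute gaze velocity and the gait speed is computed over
#' paired bins where both are available. A zero-variance input (e.g. gait
#' identically zero) yields `r = 0` with `degenerate = TRUE`.
#'
#' @param gaze gaze trace from [track_gaze()].
#' @param gait gait trace from [decode_quadrature()] (or any data frame
#'   with `t_start` and `speed` 1 s bins).
#' @param bin_width bin width, s.
#' @return list with `r`, `n`, `degenerate` and the paired bin table.
#' @export
correlate_gaze_gait <- function(gaze, gait, bin_width = 1) {
  gv <- gaze_velocity(gaze)
  gb <- bin_by_time(gv$t, gv$speed_deg_s, bin_width = bin_width, t0 = 0)
  gaitb <- if (!is.null(gait$speed_bins)) gait$speed_bins else gait
  m <- merge(data.frame(t_start = gb$t_start, gaze_speed = gb$mean),
             data.frame(t_start = gaitb$t_start, gait_speed = gaitb$speed),
             by = "t_start")
  m <- m[is.finite(m$gaze_speed) & is.finite(m$gait_speed), ]
  if (nrow(m) < 3) stop("fewer than 3 paired bins", call. = FALSE)
  degenerate <- sd(m$gaze_speed) == 0 || sd(m$gait_speed) == 0
  r <- if (degenerate) 0 else cor(m$gaze_speed, m$gait_speed)
  list(r = r, n = nrow(m), degenerate = degenerate, pairs = m)
}
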