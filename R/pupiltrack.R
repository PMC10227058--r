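# Pupil segmentation, trace gating and beam-clipping geometry.
#
# The exit pupil is the low-spatial-texture region of the pupil-camera
# frame: a local standard-deviation filter highlights it, thresholding at
# STD < 0.25 (on [0,1]-normalized intensities) gives candidate regions,
# watershed separates touching regions, and the selected region's contour
# is fitted with a direct least-squares ellipse.

#' Pupil-tracking configuration
#'
#' @param std_window side of the local texture window, px (odd, >= 3).
#' @param std_threshold texture threshold on the \[0,1\] intensity scale;
#'   pixels with local STD below it are pupil candidates (default 0.25).
#' @param max_center_jump causal gate: maximum plausible center displacement
#'   per frame, px (default 50).
#' @param max_size_jump causal gate: maximum plausible fractional area
#'   change per frame (default 0.5).
#' @param min_area_frac,max_area_frac absolute sanity bounds on region area
#'   as a fraction of the frame (defaults 0.01 and 0.60).
#' @return An object of class `pupil_config`.
#' @export
pupil_config <- function(std_window = 7, std_threshold = 0.25,
                         max_center_jump = 50, max_size_jump = 0.5,
                         min_area_frac = 0.01, max_area_frac = 0.60) {
  if (std_window < 3 || std_window %% 2 == 0)
    stop("`std_window` must be odd and >= 3", call. = FALSE)
  if (std_threshold <= 0 || std_threshold >= 1)
    stop("`std_threshold` must be in (0, 1)", call. = FALSE)
  structure(list(std_window = std_window, std_threshold = std_threshold,
                 max_center_jump = max_center_jump,
                 max_size_jump = max_size_jump,
                 min_area_frac = min_area_frac,
                 max_area_frac = max_area_frac),
            class = "pupil_config")
}

reflect_pad <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  ri <- c(r:1, 1:n, n:(n - r + 1))
  ci <- c(r:1, 1:m, m:(m - r + 1))
  x[ri, ci, drop = FALSE]
}

#' Local standard-deviation (texture) filter
#'
#' Each output pixel is the sample standard deviation of the `window` x
#' `window` neighborhood centered on it; borders are handled by reflection.
#'
#' @param frame numeric matrix normalized to \[0,1\].
#' @param window odd window side, px.
#' @return matrix of local standard deviations, same size as `frame`.
#' @export
std_filter <- function(frame, window = 7) {
  if (window %% 2 == 0 || window < 3)
    stop("`window` must be odd and >= 3", call. = FALSE)
  if (window > min(dim(frame)))
    stop("window larger than the frame", call. = FALSE)
  r <- (window - 1L) %/% 2L
  p <- reflect_pad(frame, r)
  n <- window^2
  s1 <- window_sums(p, window, window)
  s2 <- window_sums(p^2, window, window)
  v <- (s2 - s1^2 / n) / (n - 1)
  v[v < 0] <- 0
  sqrt(v)
}

# ---- ellipse fitting -------------------------------------------------------

# Direct least-squares ellipse fit (Fitzgibbon) to contour points.
# Returns list(cx, cy, a, b, orientation_deg) with a >= b, or NULL.
fit_ellipse <- function(x, y) {
  if (length(x) < 6) return(NULL)
  mx <- mean(x); my <- mean(y)
  sx <- max(sd(x), 1e-9); sy <- max(sd(y), 1e-9)
  xs <- (x - mx) / sx; ys <- (y - my) / sy
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  k <- which(cond > 0)
  if (!length(k)) return(NULL)
  a1 <- V[, k[1]]
  par <- c(a1, Tm %*% a1)  # A,B,C,D,E,F in scaled coords
  # un-scale: x -> (x-mx)/sx etc.
  A <- par[1] / sx^2
  B <- par[2] / (sx * sy)
  C <- par[3] / sy^2
  D <- par[4] / sx - 2 * par[1] * mx / sx^2 - par[2] * my / (sx * sy)
  E <- par[5] / sy - 2 * par[3] * my / sy^2 - par[2] * mx / (sx * sy)
  F <- par[6] + par[1] * mx^2 / sx^2 + par[3] * my^2 / sy^2 +
    par[2] * mx * my / (sx * sy) - par[4] * mx / sx - par[5] * my / sy
  conic_to_ellipse(A, B, C, D, E, F)
}

conic_to_ellipse <- function(A, B, C, D, E, F) {
  den <- B^2 - 4 * A * C
  if (den >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den
  ax2 <- -sqrt(num * (A + C - s)) / den
  if (!is.finite(ax1) || !is.finite(ax2)) return(NULL)
  th <- 0.5 * atan2(-B, C - A) * 180 / pi  # major-axis angle
  a <- max(ax1, ax2); b <- min(ax1, ax2)
  if (ax2 > ax1) th <- th + 90
  list(cx = cx, cy = cy, a = a, b = b,
       orientation = ((th + 90) %% 180) - 90)
}

region_contour <- function(mask) {
  er <- mask
  er[-1, ] <- er[-1, ] & mask[-nrow(mask), ]
  er[-nrow(mask), ] <- er[-nrow(mask), ] & mask[-1, ]
  er[, -1] <- er[, -1] & mask[, -ncol(mask)]
  er[, -ncol(mask)] <- er[, -ncol(mask)] & mask[, -1]
  which(mask & !er, arr.ind = TRUE)
}

#' Segment the pupil in one frame
#'
#' Thresholds the local-texture map (`STD < std_threshold`), separates
#' touching low-texture regions by watershed of the distance map, selects
#' the candidate region closest to the previous detection (largest within
#' the size bounds when there is none), and fits its contour with a direct
#' least-squares ellipse.
#'
#' @param frame numeric matrix, \[0,1\]-normalized.
#' @param cfg a [pupil_config()].
#' @param prev optional previous detection (list with `cx`, `cy`) used to
#'   pick the most consistent region.
#' @return list with `cx`, `cy`, semi-axes `a` >= `b`, `orientation`
#'   (degrees) and region `area` (px^2), or `NULL` when no admissible
#'   region is found (soft failure).
#' @export
segment_pupil <- function(frame, cfg = pupil_config(), prev = NULL) {
  tex <- std_filter(frame, cfg$std_window)
  mask <- tex < cfg$std_threshold
  if (!any(mask)) return(NULL)
  dm <- EBImage::distmap(EBImage::Image(t(mask) * 1))
  lab <- EBImage::watershed(dm, tolerance = 1)
  labm <- t(EBImage::imageData(lab))  # back to row = y
  nlab <- max(labm)
  if (nlab < 1) return(NULL)
  fr_area <- length(frame)
  areas <- tabulate(labm[labm > 0], nbins = nlab)
  ok <- which(areas >= cfg$min_area_frac * fr_area &
                areas <= cfg$max_area_frac * fr_area)
  if (!length(ok)) return(NULL)
  pick <- if (!is.null(prev) && is.finite(prev$cx)) {
    cent <- vapply(ok, function(l) {
      ij <- which(labm == l, arr.ind = TRUE)
      c(mean(ij[, 2]), mean(ij[, 1]))
    }, numeric(2))
    ok[which.min((cent[1, ] - prev$cx)^2 + (cent[2, ] - prev$cy)^2)]
  } else ok[which.max(areas[ok])]
  sel <- labm == pick
  ct <- region_contour(sel)
  fit <- fit_ellipse(ct[, 2], ct[, 1])
  if (is.null(fit) || fit$b <= 0) return(NULL)
  fit$area <- sum(sel)
  fit
}

#' Track the pupil through a video
#'
#' Runs [segment_pupil()] frame by frame (each detection seeds the next
#' frame's region choice) and then applies the causal outlier gates of
#' [gate_trace()].
#'
#' @param video a `video_frames` object.
#' @param cfg a [pupil_config()].
#' @param gate apply [gate_trace()] (default `TRUE`).
#' @return An ellipse trace: data frame with per-frame `t`, `cx`, `cy`,
#'   `a`, `b`, `orientation`, `area` and `valid`; frame geometry stored in
#'   attributes.
#' @export
track_pupil <- function(video, cfg = pupil_config(), gate = TRUE) {
  n <- n_frames(video)
  out <- data.frame(frame = seq_len(n), t = video$timestamps,
                    cx = NA_real_, cy = NA_real_, a = NA_real_,
                    b = NA_real_, orientation = NA_real_,
                    area = NA_real_, valid = FALSE)
  prev <- NULL
  for (k in seq_len(n)) {
    fit <- segment_pupil(get_frame(video, k), cfg, prev)
    if (!is.null(fit)) {
      out[k, c("cx", "cy", "a", "b", "orientation", "area")] <-
        c(fit$cx, fit$cy, fit$a, fit$b, fit$orientation, fit$area)
      out$valid[k] <- TRUE
      prev <- fit
    }
  }
  attr(out, "frame_dim") <- dim(video$frames)[2:3]
  attr(out, "mm_per_px") <- if (identical(video$pixel_units, "mm/px"))
    video$pixel_scale else NA_real_
  if (gate) out <- gate_trace(out, cfg)
  out
}

#' Causal outlier gating of an ellipse trace
#'
#' Removes detections with abnormally large and rapid changes: relative to
#' the last accepted frame, a center displacement above `max_center_jump`
#' px or a fractional area change above `max_size_jump` invalidates the
#' frame. The gate is seeded by the first frame passing the absolute
#' area-sanity bounds.
#'
#' @param raw ellipse trace from [track_pupil()] (>= 2 frames).
#' @param cfg a [pupil_config()].
#' @return the trace with the `valid` flags updated.
#' @export
gate_trace <- function(raw, cfg = pupil_config()) {
  if (nrow(raw) < 2) stop("trace needs >= 2 frames", call. = FALSE)
  fd <- attr(raw, "frame_dim")
  fr_area <- if (!is.null(fd)) prod(fd) else NA_real_
  sane <- function(k) {
    is.na(fr_area) ||
      (raw$area[k] >= cfg$min_area_frac * fr_area &&
         raw$area[k] <= cfg$max_area_frac * fr_area)
  }
  last <- NULL
  for (k in seq_len(nrow(raw))) {
    if (!raw$valid[k]) next
    if (is.null(last)) {
      if (sane(k)) last <- k else raw$valid[k] <- FALSE
      next
    }
    jump <- sqrt((raw$cx[k] - raw$cx[last])^2 + (raw$cy[k] - raw$cy[last])^2)
    dsize <- abs(raw$area[k] - raw$area[last]) / raw$area[last]
    if (jump > cfg$max_center_jump || dsize > cfg$max_size_jump) {
      raw$valid[k] <- FALSE
    } else {
      last <- k
    }
  }
  raw
}

# ---- beam clipping ---------------------------------------------------------

#' Instrument beam specification
#'
#' @param diameter_mm beam diameter at the pupil plane, mm (the reference
#'   instrument uses 2.0 and 1.6 mm).
#' @param mm_per_px pupil-camera scale.
#' @param center optional beam center `c(x, y)` in px; defaults to the mean
#'   valid pupil center of the analyzed trace.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(diameter_mm, mm_per_px, center = NULL) {
  if (diameter_mm <= 0) stop("beam diameter must be > 0", call. = FALSE)
  structure(list(diameter_mm = diameter_mm, mm_per_px = mm_per_px,
                 center = center),
            class = "beam_spec")
}

# Area of intersection of the polygon (px, py) with the circle of radius r
# centered at the origin (Green's theorem with circular-arc substitution).
poly_circle_area <- function(px, py, r) {
  n <- length(px)
  Ax <- px; Ay <- py
  Bx <- c(px[-1], px[1]); By <- c(py[-1], py[1])
  dx <- Bx - Ax; dy <- By - Ay
  a <- dx^2 + dy^2
  b <- 2 * (Ax * dx + Ay * dy)
  cc <- Ax^2 + Ay^2 - r^2
  disc <- b^2 - 4 * a * cc
  sq <- sqrt(pmax(disc, 0))
  s1 <- ifelse(disc > 0 & a > 0, (-b - sq) / (2 * a), 0)
  s2 <- ifelse(disc > 0 & a > 0, (-b + sq) / (2 * a), 0)
  s1 <- pmin(pmax(s1, 0), 1); s2 <- pmin(pmax(s2, 0), 1)
  lo <- pmin(s1, s2); hi <- pmax(s1, s2)
  contrib <- function(sa, sb) {
    P1x <- Ax + sa * dx; P1y <- Ay + sa * dy
    P2x <- Ax + sb * dx; P2y <- Ay + sb * dy
    mx <- Ax + (sa + sb) / 2 * dx; my <- Ay + (sa + sb) / 2 * dy
    cr <- P1x * P2y - P1y * P2x
    dt <- P1x * P2x + P1y * P2y
    ifelse(mx^2 + my^2 <= r^2, cr / 2, r^2 / 2 * atan2(cr, dt))
  }
  tot <- contrib(rep(0, n), lo) + contrib(lo, hi) + contrib(hi, rep(1, n))
  abs(sum(tot))
}

# Intersection area of a circle (center cx,cy radius r) with an ellipse
# (center ex,ey semi-axes a>=b, orientation deg). The ellipse is mapped to
# the unit circle; the beam circle maps to a polygon (default 2048-gon)
# whose intersection with the unit disc is computed exactly edge-by-edge.
circle_ellipse_intersection <- function(cx, cy, r, ex, ey, a, b,
                                        orientation_deg, n_vertices = 2048) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  bx <- cx + r * cos(th); by <- cy + r * sin(th)
  ph <- orientation_deg * pi / 180
  ux <- ((bx - ex) * cos(ph) + (by - ey) * sin(ph)) / a
  uy <- (-(bx - ex) * sin(ph) + (by - ey) * cos(ph)) / b
  poly_circle_area(ux, uy, 1) * a * b
}

#' Beam-clipping report from a pupil trace
#'
#' For each valid frame the clipped fraction is
#' `1 - area(beam intersect pupil) / area(beam)`, computed by mapping the
#' pupil ellipse to a unit circle and intersecting the transformed beam
#' polygon with it. The summary reports the mean clipped percentage and
#' the fraction of frames clipped by less than 10% ("unclipped" frames;
#' a frame at exactly 10% counts as clipped).
#'
#' @param trace ellipse trace from [track_pupil()].
#' @param beam a [beam_spec()].
#' @param bin_width width of the time bins for the binned series, s.
#' @return list of class `clipping_report`: `frames` (per-frame clipped
#'   fraction), `mean_clipped_pct`, `frac_unclipped`, `binned` (1 s bins)
#'   and the beam geometry used.
#' @export
beam_clipping <- function(trace, beam, bin_width = 1) {
  v <- which(trace$valid)
  if (!length(v)) stop("no valid frames in the trace", call. = FALSE)
  mm_per_px <- beam$mm_per_px
  r_px <- beam$diameter_mm / 2 / mm_per_px
  center <- beam$center
  if (is.null(center)) center <- c(mean(trace$cx[v]), mean(trace$cy[v]))
  clipped <- rep(NA_real_, nrow(trace))
  beam_area <- pi * r_px^2
  for (k in v) {
    inter <- circle_ellipse_intersection(center[1], center[2], r_px,
                                         trace$cx[k], trace$cy[k],
                                         trace$a[k], trace$b[k],
                                         trace$orientation[k])
    clipped[k] <- min(max(1 - inter / beam_area, 0), 1)
  }
  binned <- bin_by_time(trace$t, clipped, bin_width = bin_width, t0 = 0)
  structure(list(
    frames = data.frame(frame = trace$frame, t = trace$t,
                        clipped_frac = clipped, valid = trace$valid),
    mean_clipped_pct = mean(clipped[v]) * 100,
    frac_unclipped = mean(clipped[v] < 0.10),
    binned = binned,
    beam_center_px = center, beam_radius_px = r_px,
    diameter_mm = beam$diameter_mm),
    class = "clipping_report")
}

#' @export
print.clipping_report <- function(x, ...) {
  cat(sprintf(
    "clipping_report: %.1f mm beam, mean clipped %.3f%%, %.2f%% of frames unclipped (<10%%)\n",
    x$diameter_mm, x$mean_clipped_pct, 100 * x$frac_unclipped))
  invisible(x)
}

#' Average a clipping report into 1 s time bins
#'
#' Bin boundaries are at integer multiples of `bin_width` from 0; bins with
#' no samples are reported missing (`NA`), never zero.
#'
#' @param report a `clipping_report`.
#' @param timestamps optional replacement timestamps, s.
#' @param bin_width bin width, s (default 1).
#' @return data frame of bin start time, mean clipped fraction and counts.
#' @export
bin_1s <- function(report, timestamps = NULL, bin_width = 1) {
  t <- if (is.null(timestamps)) report$frames$t else timestamps
  if (any(diff(t) <= 0)) stop("timestamps must be increasing", call. = FALSE)
  bin_by_time(t, report$frames$clipped_frac, bin_width = bin_width, t0 = 0)
}
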