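#' @importFrom stats approx coef cor fft lm mad median plogis quantile residuals rnorm runif sd var
#' @importFrom utils head read.csv tail write.csv
NULL

# ---- shared containers -----------------------------------------------------

#' Construct a video-frame stack
#'
#' Container shared by the pupil, SLO and AOSLO stages: a stack of equally
#' sized intensity frames with acquisition timing and a physical pixel scale.
#' Intensities are min-max normalized to \[0,1\] across the whole video (not
#' per frame) so that whole-video statistics such as the 60%-of-mean blink
#' rule are well defined.
#'
#' @param frames 3-d numeric array, time x rows x cols, or a list of equally
#'   sized matrices.
#' @param frame_rate frames per second (Hz), > 0.
#' @param pixel_scale physical units per pixel.
#' @param pixel_units units tag for `pixel_scale`, e.g. `"um/px"` or
#'   `"deg/px"`.
#' @param timestamps optional per-frame times in seconds; synthesized as
#'   `(k-1)/frame_rate` when absent. Must be strictly increasing.
#' @param normalize normalize intensities to \[0,1\] (default `TRUE`).
#'   Normalization is idempotent; a constant video maps to all zeros.
#' @return An object of class `video_frames`.
#' @export
video_frames <- function(frames, frame_rate, pixel_scale = 1,
                         pixel_units = "px", timestamps = NULL,
                         normalize = TRUE) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must have the same shape", call. = FALSE)
    arr <- array(0, c(length(frames), dims[[1]][1], dims[[1]][2]))
    for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
    frames <- arr
  }
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a time x rows x cols array", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("`frame_rate` must be > 0", call. = FALSE)
  n <- dim(frames)[1]
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / frame_rate
  if (length(timestamps) != n || (n > 1 && any(diff(timestamps) <= 0)))
    stop("`timestamps` must be strictly increasing, one per frame",
         call. = FALSE)
  if (normalize) frames <- normalize01(frames)
  structure(
    list(frames = frames, frame_rate = frame_rate,
         timestamps = timestamps, pixel_scale = pixel_scale,
         pixel_units = pixel_units),
    class = "video_frames")
}

#' @export
print.video_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video_frames: %d frames of %d x %d @ %.3g fps (%g %s)\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_scale, x$pixel_units))
  invisible(x)
}

#' Number of frames in a video
#' @param video a `video_frames` object.
#' @return integer frame count.
#' @export
n_frames <- function(video) dim(video$frames)[1]

#' Extract one frame as a matrix
#' @param video a `video_frames` object.
#' @param k frame index (1-based).
#' @return rows x cols numeric matrix.
#' @export
get_frame <- function(video, k) video$frames[k, , ]

#' Min-max normalize intensities to \[0,1\]
#'
#' Degenerate (constant) inputs map to all zeros rather than dividing by a
#' zero range. Applying the function twice gives the same result as once.
#'
#' @param x numeric array.
#' @return array of the same shape with values in \[0,1\].
#' @export
normalize01 <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Construct a line-scan space-time image
#'
#' A 2-d record of a repeated 1-d scan: rows are scan lines (time), columns
#' are positions along the scan axis (space). Static structure crossed by the
#' scan (a vessel wall) appears as a column; eye motion shears it; moving
#' blood cells appear as diagonal streaks.
#'
#' @param data numeric matrix, lines (time) x samples (space).
#' @param line_rate scan lines per second (Hz), default 15000.
#' @param space_scale microns per pixel along the scan axis.
#' @param theta angle in degrees between the blood vessel and the scan axis,
#'   in (0, 90\].
#' @return An object of class `space_time_image`.
#' @export
space_time_image <- function(data, line_rate = 15000, space_scale = 1,
                             theta = 90) {
  if (!is.matrix(data) || nrow(data) < 1 || ncol(data) < 1)
    stop("`data` must be a non-empty matrix (lines x space)", call. = FALSE)
  if (line_rate <= 0) stop("`line_rate` must be > 0", call. = FALSE)
  if (theta <= 0 || theta > 90)
    stop("`theta` must be in (0, 90] degrees", call. = FALSE)
  structure(list(data = data, line_rate = line_rate,
                 space_scale = space_scale, theta = theta),
            class = "space_time_image")
}

#' @export
print.space_time_image <- function(x, ...) {
  cat(sprintf(
    "space_time_image: %d lines x %d px @ %g Hz, %g um/px, theta = %g deg\n",
    nrow(x$data), ncol(x$data), x$line_rate, x$space_scale, x$theta))
  invisible(x)
}

# ---- unit conversions ------------------------------------------------------

#' Retinal magnification scale
#'
#' Conversion between retinal distance and visual angle for the mouse eye.
#' The default of 34 microns per degree is consistent with reporting a
#' 5.95 um displacement as 10.50 arc minutes (5.95 / (10.50/60) = 34.0).
#'
#' @param microns_per_degree microns of retina per degree of visual angle.
#' @return An object of class `scale_model`.
#' @export
scale_model <- function(microns_per_degree = 34.0) {
  if (microns_per_degree <= 0)
    stop("`microns_per_degree` must be positive", call. = FALSE)
  structure(list(microns_per_degree = microns_per_degree),
            class = "scale_model")
}

#' Convert retinal microns to arc minutes
#' @param um distance on the retina in microns.
#' @param scale a `scale_model`.
#' @return arc minutes of visual angle.
#' @export
um_to_arcmin <- function(um, scale = scale_model()) {
  um / scale$microns_per_degree * 60
}

#' Convert arc minutes to retinal microns
#' @param arcmin visual angle in arc minutes.
#' @param scale a `scale_model`.
#' @return microns on the retina.
#' @export
arcmin_to_um <- function(arcmin, scale = scale_model()) {
  arcmin / 60 * scale$microns_per_degree
}

# ---- file I/O --------------------------------------------------------------

#' Read a video from a multi-page TIFF
#'
#' Loads a grayscale multi-page TIFF into a [video_frames()] object with
#' per-video min-max normalization. RGB pages are averaged to gray.
#'
#' @param path path to a multi-page TIFF file. AVI containers are not
#'   readable in this toolchain; convert to TIFF first.
#' @param frame_rate frames per second.
#' @param pixel_scale,pixel_units physical pixel scale and its units.
#' @param timestamps optional explicit per-frame times (seconds).
#' @return A `video_frames` object.
#' @export
read_video <- function(path, frame_rate, pixel_scale = 1,
                       pixel_units = "px", timestamps = NULL) {
  if (!file.exists(path)) stop("cannot read video: ", path, call. = FALSE)
  if (grepl("\\.avi$", path, ignore.case = TRUE))
    stop("AVI input is not supported; supply a multi-page TIFF", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- apply(p, c(1, 2), mean)
    p
  })
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("frames of unequal shape in ", path, call. = FALSE)
  video_frames(pages, frame_rate = frame_rate, pixel_scale = pixel_scale,
               pixel_units = pixel_units, timestamps = timestamps)
}

#' Write a video to a multi-page TIFF
#' @param video a `video_frames` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  pages <- lapply(seq_len(n_frames(video)), function(k) {
    f <- get_frame(video, k)
    f[f < 0] <- 0; f[f > 1] <- 1
    f
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a per-sample trace table to CSV
#'
#' Traces are written as comma-separated values with a header row and '.'
#' decimal separator; `NA`/`NaN` quality-gated samples serialize as empty
#' fields. A round trip through [read_trace()] reproduces values to 1e-9.
#'
#' @param records a non-empty data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data frame", call. = FALSE)
  ok <- tryCatch({
    write.csv(records, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    if (file.exists(path)) unlink(path)
    stop("cannot write trace to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a trace table written by [write_trace()]
#' @param path CSV path.
#' @return data frame; empty fields restored as `NA`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("cannot read trace: ", path, call. = FALSE)
  read.csv(path, na.strings = "")
}

# ---- small shared numerics -------------------------------------------------

# Parabolic (3-point) sub-sample refinement of a discrete peak.
# y3 = values at (peak-1, peak, peak+1); returns fractional offset in (-0.5, 0.5).
peak_refine <- function(y3) {
  denom <- y3[1] - 2 * y3[2] + y3[3]
  if (!is.finite(denom) || denom >= 0) return(0)
  d <- 0.5 * (y3[1] - y3[3]) / denom
  max(-0.5, min(0.5, d))
}

# Average samples into fixed-duration time bins starting at t0.
# Returns data frame with bin start time, mean value and count; empty bins
# are kept with NA mean (missing, never zero).
bin_by_time <- function(t, x, bin_width = 1, t0 = NULL) {
  keep <- is.finite(t)
  t <- t[keep]; x <- x[keep]
  if (length(t) == 0L) stop("no finite timestamps to bin", call. = FALSE)
  if (is.null(t0)) t0 <- floor(min(t) / bin_width) * bin_width
  idx <- floor((t - t0) / bin_width) + 1L
  nb <- max(idx)
  cnt <- tabulate(idx, nbins = nb)
  valid <- is.finite(x)
  s <- rep(0, nb)
  sv <- tapply(x[valid], idx[valid], sum)
  s[as.integer(names(sv))] <- sv
  nvalid <- tabulate(idx[valid], nbins = nb)
  m <- ifelse(nvalid > 0, s / nvalid, NA_real_)
  data.frame(t_start = t0 + (seq_len(nb) - 1L) * bin_width,
             mean = m, n = cnt, n_valid = nvalid)
}

log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}
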