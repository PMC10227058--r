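# Quadrature rotary-encoder decoding of running-wheel locomotion.

#' Decode quadrature encoder channels into gait distance and speed
#'
#' 4x decoding: every edge of either channel advances a state machine over
#' the Gray sequence (A,B) = 00 -> 10 -> 11 -> 01, one signed count per
#' edge. Distance is `counts / (4 * cpr) * pi * wheel_diameter`; speed is
#' the per-bin path length divided by the covered time in the bin,
#' reported as a magnitude. Samples where both channels toggle at once are illegal
#' transitions; they are counted, contribute no movement, and more than 1%
#' of them triggers a warning.
#'
#' @param A,B 0/1 channel vectors of equal length.
#' @param sample_rate acquisition rate, Hz.
#' @param cpr encoder counts per revolution (default 256).
#' @param wheel_diameter wheel diameter, m (default 0.090).
#' @param bin_width speed bin width, s (default 1).
#' @return An object of class `gait_trace`: list with `t`, signed
#'   cumulative `distance_m`, `speed_bins` (data frame `t_start`,
#'   `speed` m/s), `total_path_m`, `illegal_fraction`, `cpr`,
#'   `wheel_diameter`.
#' @export
decode_quadrature <- function(A, B, sample_rate, cpr = 256,
                              wheel_diameter = 0.090, bin_width = 1) {
  if (length(A) != length(B))
    stop("channels must have the same length", call. = FALSE)
  if (cpr <= 0) stop("`cpr` must be > 0", call. = FALSE)
  n <- length(A)
  # state index on the Gray cycle 00,10,11,01 -> 0,1,2,3
  s <- ifelse(A == 1 & B == 0, 1L,
              ifelse(A == 1 & B == 1, 2L, ifelse(A == 0 & B == 1, 3L, 0L)))
  d <- (s[-1] - s[-n]) %% 4L
  step <- integer(n - 1L)
  step[d == 1L] <- 1L
  step[d == 3L] <- -1L
  illegal <- d == 2L
  if (mean(illegal) > 0.01)
    warning(sprintf("%.1f%% illegal quadrature transitions",
                    100 * mean(illegal)))
  counts <- c(0L, cumsum(step))
  per_count_m <- pi * wheel_diameter / (4 * cpr)
  distance <- counts * per_count_m
  t <- (seq_len(n) - 1) / sample_rate
  path <- c(0, abs(step)) * per_count_m  # unsigned per-sample path length
  pb <- bin_by_time(t, path, bin_width = bin_width, t0 = 0)
  # per-bin path over covered time (mean path per sample x sample rate),
  # so partially covered trailing bins are not biased low; bins covering
  # less than 10% of the bin width cannot resolve an edge rate -> NA
  min_cov <- 0.1 * bin_width * sample_rate
  speed <- ifelse(pb$n >= min_cov, pb$mean * sample_rate, NA_real_)
  structure(list(t = t, distance_m = distance,
                 speed_bins = data.frame(t_start = pb$t_start, speed = speed),
                 total_path_m = sum(path),
                 illegal_fraction = mean(illegal),
                 cpr = cpr, wheel_diameter = wheel_diameter,
                 sample_rate = sample_rate),
            class = "gait_trace")
}

#' @export
print.gait_trace <- function(x, ...) {
  cat(sprintf(
    "gait_trace: %.1f s, total path %.3f m, peak 1 s speed %.3f m/s\n",
    max(x$t), x$total_path_m, max(x$speed_bins$speed, na.rm = TRUE)))
  invisible(x)
}

#' Pair imaging timestamps with gait speed bins
#'
#' For every imaging timestamp, the gait-speed bin containing it is
#' attached; samples outside the gait record are paired with `NA`
#' (missing, never zero). Non-overlapping records are an error.
#'
#' @param gait a `gait_trace` from [decode_quadrature()].
#' @param imaging_timestamps imaging sample times, s.
#' @return data frame with `t`, `bin_t_start`, `gait_speed`.
#' @export
synchronize <- function(gait, imaging_timestamps) {
  sb <- gait$speed_bins
  bw <- if (nrow(sb) > 1) diff(sb$t_start[1:2]) else 1
  lo <- sb$t_start[1]; hi <- sb$t_start[nrow(sb)] + bw
  if (max(imaging_timestamps) < lo || min(imaging_timestamps) > hi)
    stop("imaging and gait records do not overlap", call. = FALSE)
  idx <- floor((imaging_timestamps - sb$t_start[1]) / bw) + 1L
  ok <- idx >= 1 & idx <= nrow(sb)
  data.frame(t = imaging_timestamps,
             bin_t_start = ifelse(ok, sb$t_start[pmax(idx, 1L)], NA_real_),
             gait_speed = ifelse(ok, sb$speed[pmax(idx, 1L)], NA_real_))
}
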