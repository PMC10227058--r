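# End-to-end orchestration: run named figure-level recipes on synthetic
# data with known ground truth and emit a machine-readable report.

#' Run the synthetic analysis pipeline
#'
#' Executes the selected stages in dependency order on internally
#' generated synthetic data, collects per-stage summary statistics
#' (recovered vs true quantities) and writes a JSON report. All
#' randomness derives from `seed`; re-running with the same seed gives
#' identical numeric output. An empty stage list is a valid no-op.
#'
#' @param stages character vector from `c("pupil", "gaze", "register",
#'   "tremor", "flow", "oct", "gait")`.
#' @param seed master seed.
#' @param out_dir optional directory; when given, the report is written to
#'   `out_dir/report.json` and stage traces to CSV.
#' @param scale size multiplier for the synthetic problems (1 = desk
#'   scale).
#' @return the report, a named list (invisibly written to JSON).
#' @export
run_pipeline <- function(stages = character(), seed = 1, out_dir = NULL,
                         scale = 1) {
  report <- list(seed = seed, stages = as.list(stages),
                 package_version = as.character(utils::packageVersion("awakeretina")))
  results <- list()
  for (st in stages) {
    results[[st]] <- switch(
      st,
      pupil = pipeline_pupil(seed, scale),
      gaze = pipeline_gaze(seed, scale),
      register = pipeline_register(seed, scale),
      tremor = pipeline_tremor(seed, scale),
      flow = pipeline_flow(seed, scale),
      oct = pipeline_oct(seed, scale),
      gait = pipeline_gait(seed, scale),
      stop("unknown stage: ", st, call. = FALSE))
    log_msg(st, "done")
  }
  report$results <- results
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

pipeline_pupil <- function(seed, scale = 1) {
  sc <- pupil_scene(drift = c(0.3, 0.15), seed = seed)
  g <- gen_pupil_video(sc, n_frames = max(20, round(20 * scale)))
  tr <- track_pupil(g$video)
  rep20 <- beam_clipping(tr, beam_spec(2.0, sc$mm_per_px))
  rep16 <- beam_clipping(tr, beam_spec(1.6, sc$mm_per_px))
  v <- tr$valid
  list(n_frames = n_frames(g$video),
       n_valid = sum(v),
       center_rmse_px = sqrt(mean((tr$cx[v] - g$truth$cx[v])^2 +
                                    (tr$cy[v] - g$truth$cy[v])^2)),
       mean_clipped_pct_2mm = rep20$mean_clipped_pct,
       mean_clipped_pct_1p6mm = rep16$mean_clipped_pct,
       frac_unclipped_2mm = rep20$frac_unclipped,
       frac_unclipped_1p6mm = rep16$frac_unclipped)
}

pipeline_gaze <- function(seed, scale = 1) {
  n <- max(60, round(60 * scale))
  with_seed(substream_seed(seed, "gaze-motion"), {
    mx <- cumsum(rnorm(n, 0, 0.05))
    my <- cumsum(rnorm(n, 0, 0.05))
  })
  g <- gen_slo_video(cbind(mx, my), blink_frames = c(20, 21), seed = seed)
  tpl <- template_set(g$video, list(c(20, 20, 40, 40), c(90, 30, 40, 40),
                                    c(40, 90, 40, 40)))
  bl <- detect_blinks(g$video)
  tr <- track_gaze(g$video, tpl, blinks = bl)
  wn <- window_normalize(tr, window = 5)
  v <- tr$valid
  # tracked offsets are relative to the template reference frame, so the
  # truth must be referenced to that frame too
  tx <- g$truth$dx_deg - g$truth$dx_deg[1]
  ty <- g$truth$dy_deg - g$truth$dy_deg[1]
  list(n_frames = n, n_blinks = sum(bl$flags),
       blink_duration_ms = if (nrow(bl$events)) bl$events$duration_s[1] * 1000
                           else NA,
       gaze_rmse_deg = sqrt(mean((tr$dx_deg[v] - tx[v])^2 +
                                   (tr$dy_deg[v] - ty[v])^2)),
       fraction_within_5deg = wn$fraction_within)
}

pipeline_register <- function(seed, scale = 1) {
  n <- max(8, round(8 * scale))
  g <- gen_aoslo_video(n_frames = n, shear_amp_px = 4, seed = seed)
  vid <- g$video
  cfg <- registration_config(search_radius = 24)
  ge <- vapply(c("none", "frame", "strip"), function(m)
    gradient_energy(render_registered(vid, cfg, mode = m)$average),
    numeric(1))
  as.list(ge)
}

pipeline_tremor <- function(seed, scale = 1) {
  tm <- tremor_model(seed = seed)
  g <- gen_linescan(duration = max(2.2, 2.2 * scale), tremor = tm,
                    seed = seed)
  tr <- extract_shear(g$st, seed = seed)
  stats <- tremor_stats(tr)
  fs <- attr(tr, "sample_rate")
  spec <- motion_spectrum(tr$w1_um, fs)
  pk <- find_spectral_peaks(spec, 1, 15, prominence = 3)
  list(amplitude_um = stats$amplitude_um,
       amplitude_arcmin = stats$amplitude_arcmin,
       low_freq_peaks_hz = pk$freq[seq_len(min(2, nrow(pk)))],
       tremor_band_power = band_power(spec, 30, 200),
       control_band_power = band_power(spec, 210, fs / 2 - 1))
}

pipeline_flow <- function(seed, scale = 1) {
  sm <- streak_model(velocities = 12, density = 2, seed = seed)
  g <- gen_linescan(duration = max(0.3, 0.3 * scale), tremor = NULL,
                    streaks = sm, noise_sd = 0.01, seed = seed)
  ser <- velocity_timecourse(g$st)
  v <- mean(ser$velocity_mm_s[ser$valid])
  d <- 40
  list(mean_velocity_mm_s = v, assumed_diameter_um = d,
       flow_ul_min = flow_rate(abs(v), d))
}

pipeline_oct <- function(seed, scale = 1) {
  nb <- max(6, round(8 * scale))
  tm0 <- matrix(205, nb, 96)
  g0 <- gen_oct_volume(tm0, seed = substream_seed(seed, "oct0"))
  g1 <- gen_oct_volume(tm0 + 8, seed = substream_seed(seed, "oct1"))
  m0 <- trt_map(segment_volume(g0$volume), g0$volume)
  m1 <- trt_map(segment_volume(g1$volume), g1$volume)
  ch <- trt_change(m1, m0)
  list(baseline_trt_um = mean(m0$trt_um, na.rm = TRUE),
       mean_change_um = ch$mean_change_um,
       pct_change = ch$pct_change)
}

pipeline_gait <- function(seed, scale = 1) {
  fs <- 100000  # > 20x the encoder edge rate at the 0.8 m/s peak
  dur <- max(6, round(6 * scale))
  t <- seq(0, dur, by = 1 / fs)
  speed <- pmin(0.8, 0.8 * t / dur)
  q <- gen_quadrature(speed, fs)
  gt <- decode_quadrature(q$A, q$B, fs)
  m <- merge(gt$speed_bins, q$truth, by = "t_start",
             suffixes = c("_est", "_true"))
  m <- m[is.finite(m$speed_est) & m$speed_true > 0.01, ]
  list(max_speed_m_s = max(gt$speed_bins$speed, na.rm = TRUE),
       speed_rel_err = mean(abs(m$speed_est - m$speed_true) / m$speed_true))
}
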