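#' @include AllClasses.R pipeline.R
NULL

# Track a simulated segment and motion-correct it against a reference mean
# position (the learning-phase mean).  Returns the corrected container and
# the motion trace set.
correctSegment <- function(k, ref_mean = NULL, learn_idx = NULL) {
  m <- trackCatheter(k, learn_idx = learn_idx)
  tr <- m$filtered
  if (is.null(ref_mean)) {
    lp <- if (is.null(learn_idx)) seq_along(tr@x_mm) else
      unique(pmin(ceiling(learn_idx / 2), length(tr@x_mm)))
    ref_mean <- c(mean(tr@x_mm[lp]), mean(tr@y_mm[lp]))
  }
  tr@x_mm <- tr@x_mm - ref_mean[1]
  tr@y_mm <- tr@y_mm - ref_mean[2]
  kc <- correctAll(k, tr, reference = "zero")
  list(k = kc, motion = m, ref_mean = ref_mean)
}

#' Hotspot recovery experiment under in-vivo-like motion
#'
#' Simulates a complete monitored ablation — learning phase, then a 60 s,
#' 30 degC-peak hotspot ramp under respiratory + cardiac motion — and
#' recovers the peak temperature with the full pipeline (tracking, per-spoke
#' motion correction, channel compression, 3 x 8 motion-state library,
#' direct k-space fit).  Only the frame windows at the end of the ramp are
#' fitted, where the true peak equals the configured peak temperature.  The
#' heating segment is simulated at its correct golden-angle schedule
#' position; the spokes between the learning phase and the evaluated windows
#' carry no information about the peak and are not generated.
#'
#' @param seed integer seed for the scene and noise.
#' @param n_pix scene grid and native matrix (74 emulates the 3 mm case of a
#'   220 mm FoV; 128 with `fov_mm = 128` the 1 mm case at desk scale).
#' @param fov_mm field of view in mm.
#' @param window_spokes spokes per temperature frame.
#' @param peak_degC true hotspot peak temperature.
#' @param ramp_s heating ramp duration, seconds.
#' @param n_learning learning spokes for the library.
#' @param n_eval_windows number of end-of-ramp windows fitted.
#' @param n_bins_resp,n_bins_card library binning (3 x 8 default).
#' @return list with `peak_true`, `peak_est`, `rel_err`, the fitted
#'   [TemperatureSeries-class] and the library bin counts.
#' @export
ablationRecoveryExperiment <- function(seed, n_pix = 74L, fov_mm = 220,
                                       window_spokes = 40L, peak_degC = 30,
                                       ramp_s = 60, n_learning = 1200L,
                                       n_eval_windows = 3L,
                                       n_bins_resp = 8L, n_bins_card = 3L) {
  tr_s <- 0.02414
  t_start <- (n_learning + 200L) * tr_s
  scene <- makeScene(sceneConfig(
    "invivo", n_pix = n_pix, fov_mm = fov_mm, n_channels = 3L, seed = seed,
    hotspot = list(t_start_s = t_start, t_ramp_s = ramp_s,
                   peak_degC = peak_degC)))
  params <- sceneParams(scene)
  res_mm <- fov_mm / n_pix

  # learning segment
  kA <- simulateAcquisition(scene, params, n_learning, seed = seed + 11L)
  segA <- correctSegment(kA, learn_idx = seq_len(n_learning))
  pw <- prewhitenAndCompress(segA$k, estimateNoise(segA$k), 0.90)

  # bin at the spoke-pair level (the tracking resolution), then expand
  pair_of <- pmin(ceiling(seq_len(n_learning) / 2), length(segA$motion$filtered@x_mm))
  labels_pair <- assignBins2d(segA$motion$respiratory@x_mm,
                              segA$motion$cardiac@z_intensity,
                              n_bins_resp, n_bins_card,
                              sample_rate_hz = 1 / (2 * tr_s))
  labels <- labels_pair[pair_of]
  lib <- buildLibrary(pw$k, labels, min_count = 15L, merge = TRUE)
  basis <- polynomialBasis(lib@matrix_size)

  # end-of-ramp segment, on the same golden-angle schedule
  end_idx <- floor((t_start + ramp_s) / tr_s)
  n_eval <- n_eval_windows * window_spokes
  kB <- simulateAcquisition(scene, params, n_eval, seed = seed + 22L,
                            start_index = end_idx - n_eval)
  segB <- correctSegment(kB, ref_mean = segA$ref_mean)
  kBc <- applyChannelModel(segB$k, pw$model)

  cfg <- fitConfig(resolution_mm = res_mm, window_spokes = window_spokes)
  series <- runSeries(kBc, lib, basis, cfg, start_spoke = 1L)

  # evaluate the last window against the exact ramp value at its centre time
  f <- length(series@times_s)
  t_mid <- series@times_s[f]
  peak_true <- peak_degC * hotspotRamp(t_mid, scene@hotspot_model)
  ctr <- scene@hotspot_model$center_mm
  x <- pixelCoords(n_pix, fov_mm)
  near <- abs(outer(x - ctr[1], rep(1, n_pix))) < 1.5 * scene@hotspot_model$sigma_mm &
    abs(outer(rep(1, n_pix), x - ctr[2])) < 1.5 * scene@hotspot_model$sigma_mm
  peak_est <- max(series@deltaT[, , f][near])
  list(peak_true = peak_true, peak_est = peak_est,
       rel_err = abs(peak_est - peak_true) / peak_true,
       series = series, bin_counts = binCounts(lib),
       resolution_mm = res_mm)
}

#' Background temperature-uncertainty experiment
#'
#' Simulates a learning phase plus an unheated stability span, builds the
#' motion-state library, and measures the paper-style background ROI
#' temperature uncertainty (mean over the ROI of each voxel's temporal SD)
#' for one or more frame window sizes, optionally with and without per-spoke
#' motion correction.
#'
#' @param seed integer seed.
#' @param kind `"phantom"` (square-wave motion, 10-bin 1D library) or
#'   `"invivo"` (respiratory + cardiac, 3 x 8 library).
#' @param windows frame window sizes (spokes) to evaluate.
#' @param n_pix scene grid / native matrix.
#' @param fov_mm field of view, mm.
#' @param n_learning,n_stability learning and stability spoke counts.
#' @param n_heating additional spokes over which the hotspot ramps (0 = the
#'   scene never heats); heated frames are part of the evaluated span, as in
#'   the motion-correction comparison of the original experiment, but the
#'   ROI always excludes the (motion-smeared) hotspot path.
#' @param noise_sigma override of the scene noise SD.
#' @param use_true_motion correct with the scene's exact displacement
#'   instead of the tracked-and-filtered curves (isolates the correction
#'   operator from tracking-filter lag at square-wave transitions).
#' @param motion_correction logical vector: evaluate with (TRUE) and/or
#'   without (FALSE) motion correction.
#' @return data frame with columns `window`, `motion_correction`,
#'   `mean_sd_degC`, `sd_sd_degC` (temporally filtered),
#'   `mean_sd_raw_degC` (per-frame, unfiltered) and `n_frames`.
#' @export
backgroundUncertaintyExperiment <- function(seed, kind = "phantom",
                                            windows = c(40L, 30L, 20L),
                                            n_pix = 74L, fov_mm = 220,
                                            n_learning = 1000L,
                                            n_stability = 1000L,
                                            n_heating = 0L,
                                            noise_sigma = NULL,
                                            use_true_motion = FALSE,
                                            motion_correction = TRUE) {
  tr_s <- 0.02414
  n_total <- n_learning + n_stability + n_heating
  heat_start <- if (n_heating > 0) (n_learning + n_stability) * tr_s else 1e6
  scene <- makeScene(sceneConfig(
    kind, n_pix = n_pix, fov_mm = fov_mm, n_channels = 3L, seed = seed,
    hotspot = list(t_start_s = heat_start,
                   t_ramp_s = max(n_heating, 1L) * tr_s * 0.9)))
  if (!is.null(noise_sigma)) scene@noise_sigma <- noise_sigma
  params <- sceneParams(scene)
  res_mm <- fov_mm / n_pix
  k <- simulateAcquisition(scene, params, n_total, seed = seed + 31L)
  motion <- trackCatheter(k, learn_idx = seq_len(n_learning))

  # background ROI: object voxels away from the catheter coils and unheated
  # in the motion-corrected geometry (the hotspot frozen at the mean
  # position); the same ROI is used with and without correction, as one
  # region drawn on the image would be
  x <- pixelCoords(n_pix, fov_mm)
  X <- outer(x, rep(1, n_pix)); Y <- outer(rep(1, n_pix), x)
  coil <- colMeans(scene@microcoil_positions)
  hs <- scene@hotspot_model$center_mm
  md <- displacementAt(seq(0, n_learning * tr_s, by = 0.1),
                       scene@motion_model)
  hs_corr <- hs + c(mean(md$dx_mm), mean(md$dy_mm))
  roi <- scene@magnitude > 0.5 * max(scene@magnitude) &
    sqrt((X - coil[1])^2 + (Y - coil[2])^2) > 0.18 * fov_mm &
    sqrt((X - hs_corr[1])^2 + (Y - hs_corr[2])^2) >
      3 * scene@hotspot_model$sigma_mm

  corr_trace <- if (use_true_motion) {
    n_pairs <- n_total %/% 2L
    tp <- (k@times_s[2 * seq_len(n_pairs) - 1] + k@times_s[2 * seq_len(n_pairs)]) / 2
    dtrue <- displacementAt(tp, scene@motion_model)
    new("MotionTrace", times_s = tp, x_mm = dtrue$dx_mm, y_mm = dtrue$dy_mm,
        z_intensity = rep(1, n_pairs), valid = rep(TRUE, n_pairs),
        variant = "filtered", tr_s = tr_s)
  } else motion$filtered

  out <- list()
  for (mc in motion_correction) {
    kc <- if (mc) correctAll(k, corr_trace,
                             learn_idx = seq_len(n_learning)) else k
    pw <- prewhitenAndCompress(kc, estimateNoise(kc), 0.90)
    pair_of <- pmin(ceiling(seq_len(n_learning) / 2),
                    length(motion$filtered@x_mm))
    learn_pairs <- seq_len(max(pair_of))
    labels <- if (kind == "phantom") {
      assignBins1d(motion$filtered@x_mm[learn_pairs], 10L)[pair_of]
    } else {
      assignBins2d(motion$respiratory@x_mm[learn_pairs],
                   motion$cardiac@z_intensity[learn_pairs],
                   sample_rate_hz = 1 / (2 * tr_s))[pair_of]
    }
    lib <- buildLibrary(pw$k, labels, learning_idx = seq_len(n_learning),
                        min_count = 15L, merge = TRUE)
    basis <- polynomialBasis(lib@matrix_size)
    for (win in windows) {
      cfg <- fitConfig(resolution_mm = res_mm, window_spokes = as.integer(win))
      series <- runSeries(pw$k, lib, basis, cfg,
                          start_spoke = n_learning + 1L)
      rs_raw <- roiUncertainty(series, roi,
                               training_end_s = n_learning * tr_s,
                               heating_start_s = Inf)
      series_f <- temporalFilter(series)
      rs <- roiUncertainty(series_f, roi,
                           training_end_s = n_learning * tr_s,
                           heating_start_s = Inf)
      out[[length(out) + 1L]] <- data.frame(
        window = win, motion_correction = mc,
        mean_sd_degC = rs@mean_sd, sd_sd_degC = rs@sd_sd,
        mean_sd_raw_degC = rs_raw@mean_sd,
        n_frames = rs@n_frames)
    }
  }
  do.call(rbind, out)
}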