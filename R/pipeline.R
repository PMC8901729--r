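#' @include AllClasses.R simulate.R tracking.R preprocess.R library.R thermometry.R
NULL

#' Default pipeline configuration
#'
#' A plain (YAML-serialisable) list driving [runPipeline()].  Defaults
#' reproduce the phantom study conditions at desk scale: square-wave motion,
#' a 10-bin 1D library from the X motion curve, a 3 mm working resolution and
#' 40-spoke frames with `(lambda, beta) = (0.5, 0.05)`.
#'
#' @param kind `"phantom"` (square-wave motion, 1D binning) or `"invivo"`
#'   (respiratory + cardiac motion, 3 x 8 binning).
#' @param seed integer seed controlling scene and noise.
#' @param ... overrides of any entry (nested lists merged).
#' @return a named configuration list.
#' @export
pipelineConfig <- function(kind = c("phantom", "invivo"), seed = 1L, ...) {
  kind <- match.arg(kind)
  cfg <- list(
    kind = kind, seed = as.integer(seed),
    scene = list(n_pix = 96L, n_channels = 3L),
    n_learning_spokes = if (kind == "phantom") 800L else 1200L,
    n_stability_spokes = 600L,
    n_heating_spokes = 900L,
    resolution_mm = 3,
    window_spokes = 40L,
    lambda = NULL, beta = 0.05,
    variance_threshold = 0.90,
    binning = if (kind == "phantom") list(scheme = "1d", n_bins = 10L)
              else list(scheme = "2d", n_resp = 8L, n_card = 3L),
    min_bin_count = 20L,
    motion_correction = TRUE,
    temporal_cutoff_hz = 0.14,
    out_dir = NULL)
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], ov[[nm]])
    else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Run the full monitoring pipeline on a simulated acquisition
#'
#' Executes simulate -> track -> pre-whiten/compress -> motion-correct ->
#' truncate -> bin -> library -> direct k-space thermometry -> temporal
#' filter -> ROI statistics, and returns the artifacts plus a
#' machine-readable summary.  Deterministic for a fixed seed.  When
#' `config$out_dir` is set, artifacts (raw container, motion CSV, summary
#' JSON) are written there.
#'
#' @param config list from [pipelineConfig()] (or a path to a YAML file with
#'   the same structure).
#' @return invisible list with elements `kspace`, `motion`, `library`,
#'   `series`, `series_filtered`, `roi_stats`, `scene`, `summary`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  kind <- config$kind %||% "phantom"
  seed <- config$seed %||% 1L

  n_learn <- config$n_learning_spokes
  n_stab <- config$n_stability_spokes
  n_heat <- config$n_heating_spokes
  n_total <- n_learn + n_stab + n_heat
  tr <- 0.02414
  heat_start_s <- (n_learn + n_stab) * tr

  scene_args <- config$scene %||% list()
  # the run schedule fixes the default heating times; explicit scene
  # overrides still win
  hs <- modifyList(list(t_start_s = heat_start_s, t_ramp_s = n_heat * tr * 0.8),
                   scene_args$hotspot %||% list())
  scene_args$hotspot <- NULL
  scene <- makeScene(do.call(sceneConfig, c(
    list(kind = kind, seed = seed, hotspot = hs), scene_args)))
  params <- sceneParams(scene)
  k <- simulateAcquisition(scene, params, n_total, seed = seed + 1000L)

  motion <- trackCatheter(k, learn_idx = seq_len(n_learn))
  kc <- if (isTRUE(config$motion_correction %||% TRUE)) {
    correctAll(k, motion$filtered, learn_idx = seq_len(n_learn))
  } else k
  pw <- prewhitenAndCompress(kc, estimateNoise(kc),
                             config$variance_threshold %||% 0.90)
  kt <- truncateReadout(pw$k, config$resolution_mm)

  # bin at the spoke-pair level (the tracking resolution), then expand
  pair_of <- pmin(ceiling(seq_len(n_learn) / 2), length(motion$filtered@x_mm))
  learn_pairs <- seq_len(max(pair_of))
  labels <- if ((config$binning$scheme %||% "1d") == "1d") {
    assignBins1d(motion$filtered@x_mm[learn_pairs],
                 config$binning$n_bins %||% 10L)[pair_of]
  } else {
    assignBins2d(motion$respiratory@x_mm[learn_pairs],
                 motion$cardiac@z_intensity[learn_pairs],
                 config$binning$n_resp %||% 8L, config$binning$n_card %||% 3L,
                 sample_rate_hz = 1 / (2 * tr))[pair_of]
  }
  lib <- buildLibrary(kt, labels, learning_idx = seq_len(n_learn),
                      min_count = config$min_bin_count %||% 20L, merge = TRUE)
  basis <- polynomialBasis(lib@matrix_size)
  fc <- fitConfig(config$resolution_mm, config$window_spokes %||% 40L,
                  lambda = config$lambda, beta = config$beta %||% 0.05)
  series <- runSeries(kt, lib, basis, fc, start_spoke = n_learn + 1L)
  series_f <- temporalFilter(series, config$temporal_cutoff_hz %||% 0.14)

  # background ROI: unheated object quadrant opposite the hotspot
  N <- lib@matrix_size
  x <- pixelCoords(N, params@fov_mm)
  X <- outer(x, rep(1, N)); Y <- outer(rep(1, N), x)
  hs <- scene@hotspot_model$center_mm
  mag_low <- abs(lib@images[, , 1, 1])
  roi <- mag_low > 0.3 * max(mag_low) &
    sqrt((X - hs[1])^2 + (Y - hs[2])^2) > 4 * scene@hotspot_model$sigma_mm
  roi_stats <- roiUncertainty(series_f, roi, n_learn * tr, heat_start_s)

  peak_frame <- which.min(abs(series_f@times_s -
                                (heat_start_s + scene@hotspot_model$t_ramp_s)))
  obj <- abs(lib@images[, , 1, 1])
  obj_mask <- obj > 0.35 * max(obj)
  # headline peak: 3x3-average-filtered map, robust to single-voxel noise
  box3 <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    acc <- matrix(0, n1, n2); cnt <- matrix(0, n1, n2)
    for (dx in -1:1) for (dy in -1:1) {
      sr <- max(1, 1 + dx):min(n1, n1 + dx); tr <- max(1, 1 - dx):min(n1, n1 - dx)
      sc <- max(1, 1 + dy):min(n2, n2 + dy); tc <- max(1, 1 - dy):min(n2, n2 - dy)
      acc[tr, tc] <- acc[tr, tc] + m[sr, sc]
      cnt[tr, tc] <- cnt[tr, tc] + 1
    }
    acc / cnt
  }
  peak_map <- box3(series_f@deltaT[, , peak_frame])
  summary <- list(
    kind = kind, seed = seed,
    n_spokes = n_total, run_length_s = n_total * tr,
    tracking_resolution_s = 2 * tr,
    frame_spacing_s = fc@stride_spokes * tr,
    acceleration = accelerationFactor(fc@window_spokes,
                                      resolution_mm = config$resolution_mm,
                                      fov_mm = params@fov_mm),
    matrix_size = N,
    n_bins = length(binCounts(lib)),
    bin_counts = as.integer(binCounts(lib)),
    retained_channels = pw$model@n_out,
    retained_variance = pw$model@retained_variance,
    lambda = fc@lambda_sparsity, beta = fc@beta_roughness,
    roi_mean_sd_degC = roi_stats@mean_sd,
    roi_sd_sd_degC = roi_stats@sd_sd,
    peak_deltaT_degC = max(peak_map[obj_mask]),
    package_version = as.character(utils::packageVersion("radialtherm")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeRaw(k, file.path(config$out_dir, "raw.rds"))
    mo <- motion$filtered
    write.csv(data.frame(time_s = mo@times_s, x_mm = mo@x_mm, y_mm = mo@y_mm,
                         z_intensity = mo@z_intensity, variant = mo@variant),
              file.path(config$out_dir, "motion.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(kspace = k, motion = motion, library = lib, series = series,
                 series_filtered = series_f, roi_stats = roi_stats,
                 scene = scene, summary = summary))
}
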