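#' @include AllClasses.R raw_io.R
NULL

#' Scene configuration presets
#'
#' Builds the configuration list consumed by [makeScene()].  Two presets
#' emulate the experimental conditions the package targets:
#' \describe{
#'   \item{`"phantom"`}{an agar-gel-like cylinder on a pneumatic trolley
#'     switching between two positions 26 mm apart along x at 0.33 Hz
#'     (square-wave motion), heated by a catheter-tip RF source.}
#'   \item{`"invivo"`}{free-breathing conditions: respiratory sinusoidal
#'     motion at 0.25 Hz (15 breaths/min, peak amplitudes 4.5 / 2.12 mm in
#'     x / y) plus a cardiac component at 0.825 Hz (1.92 / 1.52 mm), with a
#'     cardiac out-of-plane excursion that modulates the micro-coil signal
#'     intensity.}
#' }
#' Amplitudes of sinusoidal components are peak values of the mean-centred
#' displacement; the square-wave amplitude is the distance between the two
#' plateaus.  All values are configurable through `...`.
#'
#' @param kind `"phantom"` or `"invivo"`.
#' @param n_pix scene grid size (desk-scale default 128; all sizes allowed).
#' @param fov_mm field of view in mm.
#' @param n_channels number of imaging channels.
#' @param seed integer seed fully determining the scene.
#' @param ... overrides for any configuration entry (`motion`, `hotspot`,
#'   `background`, `drift_rad_per_s`, `noise_sigma`, `coil`,
#'   `microcoil_positions`, ...).
#' @return a named list understood by [makeScene()].
#' @export
sceneConfig <- function(kind = c("phantom", "invivo"), n_pix = 128L,
                        fov_mm = 220, n_channels = 4L, seed = 1L, ...) {
  kind <- match.arg(kind)
  motion <- if (kind == "phantom") {
    list(kind = "square_wave", amplitude_mm = c(26, 0), freq_hz = 0.33,
         rise_time_s = 0.1)
  } else {
    list(kind = "resp_cardiac",
         resp_amp_mm = c(4.5, 2.12), resp_freq_hz = 0.25,
         card_amp_mm = c(1.92, 1.52), card_freq_hz = 0.825,
         card_phase = pi / 3, card_z_amp_mm = 1)
  }
  hotspot <- list(center_mm = c(0.12, -0.04) * fov_mm, sigma_mm = 5,
                  peak_degC = 30,
                  t_start_s = if (kind == "phantom") 90 else 120,
                  t_ramp_s = 60, decay_tau_s = 120)
  base <- list(
    kind = kind, n_pix = as.integer(n_pix), fov_mm = fov_mm,
    n_channels = as.integer(n_channels), seed = as.integer(seed),
    motion = motion, hotspot = hotspot,
    microcoil_positions = rbind(proximal = c(0.10, 0.07) * fov_mm,
                                distal   = c(0.12, -0.01) * fov_mm),
    background = list(order = 2, static_rms_rad = 0.5, coupled_rms_rad = 0.3),
    drift_rad_per_s = 0.005,
    noise_sigma = 5,
    coil = list(amplitude = 40, footprint_px = 2, z_sigma_mm = 1.5))
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(base[[nm]]) && is.list(ov[[nm]]))
      base[[nm]] <- modifyList(base[[nm]], ov[[nm]])
    else base[[nm]] <- ov[[nm]]
  }
  base
}

smoothSquareState <- function(t, freq_hz, rise_time_s) {
  k <- max(pi * freq_hz * rise_time_s, 1e-6)
  raw <- function(tt) 0.5 * (1 - tanh(cos(2 * pi * freq_hz * tt) / k))
  s0 <- raw(0)                       # reference plateau
  s1 <- 0.5 * (1 + tanh(1 / k))     # opposite plateau
  pmin(pmax((raw(t) - s0) / (s1 - s0), 0), 1)
}

#' Rigid in-plane displacement at time t
#'
#' Evaluates the scene's parametric motion model.  The square-wave kind
#' alternates between the reference position and a plateau `amplitude_mm`
#' away, with transitions smoothed over the stated rise time; the
#' respiratory + cardiac kind is a sum of two sinusoids per axis.  At `t = 0`
#' every model is at its reference position.
#'
#' @param t time(s) in seconds (vectorised).
#' @param motion_model the `motion_model` list of a [PhantomScene-class]
#'   (or a [PhantomScene-class], whose model is then used).
#' @return list with numeric vectors `dx_mm` and `dy_mm`.
#' @export
displacementAt <- function(t, motion_model) {
  if (is(motion_model, "PhantomScene")) motion_model <- motion_model@motion_model
  m <- motion_model
  stopifnot(all(t >= 0))
  if (m$kind == "square_wave") {
    s <- smoothSquareState(t, m$freq_hz, m$rise_time_s %||% 0.1)
    list(dx_mm = m$amplitude_mm[1] * s, dy_mm = m$amplitude_mm[2] * s)
  } else if (m$kind == "resp_cardiac") {
    wr <- 2 * pi * m$resp_freq_hz
    wc <- 2 * pi * m$card_freq_hz
    pc <- m$card_phase %||% 0
    list(dx_mm = m$resp_amp_mm[1] * sin(wr * t) +
           m$card_amp_mm[1] * sin(wc * t + pc) - m$card_amp_mm[1] * sin(pc),
         dy_mm = m$resp_amp_mm[2] * sin(wr * t) +
           m$card_amp_mm[2] * sin(wc * t + pc) - m$card_amp_mm[2] * sin(pc))
  } else if (m$kind == "none") {
    z <- rep(0, length(t))
    list(dx_mm = z, dy_mm = z)
  } else stop("unknown motion kind: ", m$kind)
}

#' Displacement-scaled motion state
#'
#' Drives the motion-state-dependent part of the background phase: the
#' displacement magnitude in units of a 20 mm reference excursion, so the
#' susceptibility-like phase coupling scales with how far the object
#' actually moved (and vanishes with the motion amplitude).
#' @inheritParams displacementAt
#' @keywords internal
motionStateAt <- function(t, motion_model) {
  d <- displacementAt(t, motion_model)
  sqrt(d$dx_mm^2 + d$dy_mm^2) / 20
}

coilZOffsetAt <- function(t, motion_model) {
  m <- motion_model
  if (identical(m$kind, "resp_cardiac") && !is.null(m$card_z_amp_mm) &&
      m$card_z_amp_mm > 0) {
    m$card_z_amp_mm * sin(2 * pi * m$card_freq_hz * t + (m$card_phase %||% 0))
  } else rep(0, length(t))
}

#' Hotspot temperature time course (fraction of peak)
#'
#' Zero before ramp start, linear to 1 over the ramp, then exponential decay.
#' @param t time(s) in seconds.
#' @param hotspot_model hotspot list of a scene.
#' @return fraction of the peak temperature, in `[0, 1]`.
#' @export
hotspotRamp <- function(t, hotspot_model) {
  h <- hotspot_model
  f <- numeric(length(t))
  ramping <- t >= h$t_start_s & t < h$t_start_s + h$t_ramp_s
  f[ramping] <- (t[ramping] - h$t_start_s) / h$t_ramp_s
  after <- t >= h$t_start_s + h$t_ramp_s
  f[after] <- exp(-(t[after] - h$t_start_s - h$t_ramp_s) / h$decay_tau_s)
  f
}

lowOrderPolyMap <- function(n_pix, order, rms_rad, seed_offset, seed) {
  # deterministic random low-order polynomial phase map with a given RMS
  # over the central disk
  set.seed(seed + seed_offset)
  u <- (seq_len(n_pix) - 1 - n_pix / 2) / (n_pix / 2)
  X <- outer(u, rep(1, n_pix))
  Y <- outer(rep(1, n_pix), u)
  map <- matrix(0, n_pix, n_pix)
  for (p in 0:order) for (q in 0:(order - p)) {
    map <- map + rnorm(1) * X^p * Y^q
  }
  disk <- X^2 + Y^2 < 0.7^2
  map * rms_rad / sd(map[disk])
}

#' Build a synthetic phantom scene
#'
#' Constructs the full ground-truth scene from a [sceneConfig()] list: a
#' smooth compact magnitude object with internal structure, smooth complex
#' coil sensitivities, two micro-coil positions, and the motion, hotspot,
#' background-phase, drift and noise models.  Deterministic for a fixed seed.
#'
#' @param config a list from [sceneConfig()].
#' @return a [PhantomScene-class].
#' @examples
#' sc <- makeScene(sceneConfig("phantom", n_pix = 64, seed = 2))
#' range(displacementAt(c(0, 1/(2 * 0.33)), sc)$dx_mm)  # the two plateaus
#' @export
makeScene <- function(config = sceneConfig()) {
  stopifnot(is.list(config), !is.null(config$motion$kind), !is.null(config$hotspot))
  n <- config$n_pix
  fov <- config$fov_mm
  if (!is.null(config$hotspot$sigma_mm) && config$hotspot$sigma_mm <= 0)
    stop("hotspot sigma_mm must be positive")
  if (any(abs(config$hotspot$center_mm) > fov / 2))
    stop("hotspot center lies outside the FoV")
  set.seed(config$seed)
  x <- pixelCoords(n, fov)
  X <- outer(x, rep(1, n))
  Y <- outer(rep(1, n), x)
  R <- sqrt(X^2 + Y^2)

  # compact object: smooth-edged disk with a few internal bumps and holes
  mag <- 0.5 * (1 + tanh((0.38 * fov - R) / (0.03 * fov)))
  for (b in seq_len(4)) {
    cx <- runif(1, -0.2, 0.2) * fov; cy <- runif(1, -0.2, 0.2) * fov
    sg <- runif(1, 0.04, 0.10) * fov
    amp <- runif(1, -0.35, 0.5)
    mag <- mag + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
  }
  mag <- pmax(mag, 0)
  mag[mag < 1e-4 * max(mag)] <- 0   # compact support (speeds the exact NDFT)

  # smooth complex sensitivities: Gaussian lobes around the FoV border
  nc <- config$n_channels
  sens <- array(0i, c(n, n, nc))
  for (ch in seq_len(nc)) {
    th <- 2 * pi * (ch - 1) / nc + runif(1, -0.2, 0.2)
    cx <- 0.45 * fov * cos(th); cy <- 0.45 * fov * sin(th)
    sg <- 0.5 * fov
    magc <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
    ph <- (runif(1, -1, 1) * X + runif(1, -1, 1) * Y) / fov +
      runif(1, -0.5, 0.5) * (X * Y) / fov^2
    sens[, , ch] <- magc * exp(1i * ph)
  }

  bg <- list(
    static = lowOrderPolyMap(n, config$background$order,
                             config$background$static_rms_rad, 101L, config$seed),
    motion_coupled = lowOrderPolyMap(n, config$background$order,
                                     config$background$coupled_rms_rad, 202L,
                                     config$seed))

  coil <- config$coil
  coil$footprint_mm <- coil$footprint_px * fov / n

  new("PhantomScene",
      magnitude = mag, sensitivities = sens,
      microcoil_positions = config$microcoil_positions,
      motion_model = config$motion, hotspot_model = config$hotspot,
      background_phase_model = bg,
      drift_rad_per_s = config$drift_rad_per_s,
      coil_model = coil,
      noise_sigma = config$noise_sigma,
      fov_mm = fov, n_pix = as.integer(n), seed = as.integer(config$seed))
}

#' Acquisition parameters matched to a scene
#'
#' Convenience constructor: native matrix equal to the scene grid, readout
#' length `oversampling * n_pix`, and the scene's FoV; other parameters as
#' [acquisitionParams()].
#' @param scene a [PhantomScene-class].
#' @param oversampling readout oversampling factor.
#' @param ... passed to [acquisitionParams()].
#' @export
sceneParams <- function(scene, oversampling = 2, ...) {
  acquisitionParams(fov_mm = scene@fov_mm,
                    n_readout = as.integer(oversampling * scene@n_pix),
                    oversampling = oversampling,
                    matrix_size = scene@n_pix, ...)
}

#' PRF phase-per-degree constant
#'
#' `2 * pi * gamma * B0 * alpha * 1e-6 * TE` radians per degree C (negative
#' for water, whose resonance shifts down on heating).
#' @param params an [AcquisitionParams-class].
#' @export
prfRadPerDegC <- function(params) {
  2 * pi * params@gamma_hz_per_tesla * params@b0_tesla *
    params@prf_alpha_ppm_per_degC * 1e-6 * params@te_s
}

#' Ground-truth temperature-change map of a scene
#'
#' @param scene a [PhantomScene-class].
#' @param t time in seconds.
#' @return matrix of the exact temperature change (degrees C) at `t`, in the
#'   motion-compensated object frame.
#' @export
hotspotDeltaT <- function(scene, t) {
  h <- scene@hotspot_model
  x <- pixelCoords(scene@n_pix, scene@fov_mm)
  X <- outer(x, rep(1, scene@n_pix))
  Y <- outer(rep(1, scene@n_pix), x)
  shape <- exp(-((X - h$center_mm[1])^2 + (Y - h$center_mm[2])^2) / (2 * h$sigma_mm^2))
  h$peak_degC * hotspotRamp(t, h) * shape
}

#' Ground-truth temperature series
#'
#' Exact temperature-change maps of the scene at the requested frame times,
#' in the motion-compensated object frame; the oracle for recovery tests.
#'
#' @param scene a [PhantomScene-class].
#' @param frame_times sorted frame times, seconds.
#' @param params optional [AcquisitionParams-class] (default [sceneParams()]).
#' @return a [TemperatureSeries-class] (with exact `theta` and `deltaT`).
#' @export
groundTruthSeries <- function(scene, frame_times, params = sceneParams(scene)) {
  stopifnot(!is.unsorted(frame_times))
  n <- scene@n_pix
  nf <- length(frame_times)
  dT <- array(0, c(n, n, nf))
  for (f in seq_len(nf)) dT[, , f] <- hotspotDeltaT(scene, frame_times[f])
  new("TemperatureSeries",
      theta = dT * prfRadPerDegC(params), deltaT = dT,
      times_s = as.numeric(frame_times),
      spoke_idx = vector("list", nf),
      w = matrix(numeric(0), 0, nf), c = matrix(numeric(0), 0, nf),
      converged = rep(TRUE, nf),
      window_spokes = 0L, stride_spokes = 0L, params = params)
}

#' Simulate a multi-channel golden-angle radial acquisition
#'
#' Samples the scene along golden-angle radial spokes by exact non-uniform
#' discrete Fourier transform.  For each spoke at its acquisition time
#' `t_m = (start_index + m) * TR`:
#' \enumerate{
#'   \item the rigid displacement `displacementAt(t_m)` is applied exactly as
#'     a k-space phase ramp along the spoke (Fourier shift theorem) — never by
#'     image interpolation — so the simulator is an exact oracle for the
#'     motion-correction operator;
#'   \item the object phase is the motion-state background phase plus
#'     `drift * t_m` plus the PRF heating phase
#'     `prfRadPerDegC(params) * deltaT(t_m, r)`;
#'   \item each imaging channel samples the sensitivity-weighted object; each
#'     micro-coil channel is a point source at the displaced coil position
#'     with a compact Gaussian footprint, attenuated by its out-of-plane
#'     offset;
#'   \item i.i.d. complex Gaussian noise of SD `noise_sigma` is added
#'     (per real/imaginary component, all channels).
#' }
#'
#' @param scene a [PhantomScene-class].
#' @param params an [AcquisitionParams-class]; its matrix size must equal the
#'   scene grid.
#' @param n_spokes number of spokes to simulate.
#' @param seed noise seed (the scene seed only shapes the scene).
#' @param start_index global index of the first spoke (angles and times
#'   continue the golden-angle schedule from there).
#' @param angles_deg optional explicit per-spoke angles (overrides the
#'   golden-angle schedule; length `n_spokes`).
#' @param extra_shift_mm constant additional rigid shift `(dx, dy)` applied on
#'   top of the motion model (used by shift-theorem oracle tests).
#' @param noise_sigma override of the scene's noise SD (e.g. 0 for noiseless).
#' @return a [RadialKspace-class] with imaging channels followed by the
#'   proximal and distal micro-coil channels (flagged in the channel roles).
#' @export
simulateAcquisition <- function(scene, params = sceneParams(scene), n_spokes,
                                seed = 1L, start_index = 0L, angles_deg = NULL,
                                extra_shift_mm = c(0, 0),
                                noise_sigma = scene@noise_sigma) {
  stopifnot(n_spokes >= 1)
  if (params@matrix_size != scene@n_pix)
    stop("scene grid (", scene@n_pix, ") and params matrix size (",
         params@matrix_size, ") are inconsistent")
  n_read <- params@n_readout
  fov <- params@fov_mm
  idx <- start_index + seq_len(n_spokes) - 1
  if (is.null(angles_deg)) angles_deg <- idx * GOLDEN_ANGLE_DEG
  stopifnot(length(angles_deg) == n_spokes)
  times <- idx * params@tr_s
  rho <- (angles_deg %% 360) * pi / 180
  dk <- params@k_spacing_cyc_fov
  kr <- (seq_len(n_read) - 1 - n_read / 2) * dk

  # voxel support
  n <- scene@n_pix
  x <- pixelCoords(n, fov)
  X <- outer(x, rep(1, n)); Y <- outer(rep(1, n), x)
  mask <- scene@magnitude > 1e-9 * max(scene@magnitude)
  ux <- X[mask] / fov; uy <- Y[mask] / fov
  nc <- dim(scene@sensitivities)[3]
  sens <- matrix(0i, sum(mask), nc)
  for (ch in seq_len(nc)) sens[, ch] <- scene@sensitivities[, , ch][mask]

  h <- scene@hotspot_model
  heat_shape <- exp(-((X - h$center_mm[1])^2 + (Y - h$center_mm[2])^2) /
                      (2 * h$sigma_mm^2))[mask]
  prf <- prfRadPerDegC(params)
  a_t <- prf * h$peak_degC * hotspotRamp(times, h)
  s_t <- motionStateAt(times, scene@motion_model)
  phi0_t <- scene@drift_rad_per_s * times
  d <- displacementAt(times, scene@motion_model)
  dxf <- (d$dx_mm + extra_shift_mm[1]) / fov
  dyf <- (d$dy_mm + extra_shift_mm[2]) / fov

  img <- ndft_simulate(scene@magnitude[mask], sens,
                       scene@background_phase_model$static[mask],
                       scene@background_phase_model$motion_coupled[mask],
                       heat_shape, ux, uy, kr, rho, s_t, a_t, phi0_t, dxf, dyf)
  # img: n_read x n_spokes x nc; reorder to spokes x read x chan
  data <- array(0i, c(n_spokes, n_read, nc + 2L))
  for (ch in seq_len(nc)) data[, , ch] <- t(img[, , ch])

  # micro-coil channels: point source with Gaussian footprint, analytic
  coil <- scene@coil_model
  sig_u <- coil$footprint_mm / fov
  fdecay <- exp(-2 * pi^2 * sig_u^2 * kr^2)
  zoff <- coilZOffsetAt(times, scene@motion_model)
  atten <- exp(-zoff^2 / (2 * coil$z_sigma_mm^2))
  for (cc in 1:2) {
    p0 <- scene@microcoil_positions[cc, ]
    px <- (p0[1] + d$dx_mm + extra_shift_mm[1]) / fov
    py <- (p0[2] + d$dy_mm + extra_shift_mm[2]) / fov
    up <- px * cos(rho) + py * sin(rho)           # per spoke, FoV units
    phase <- exp(-2i * pi * outer(up, kr))        # spokes x read
    data[, , nc + cc] <- coil$amplitude * atten * phase *
      matrix(fdecay, n_spokes, n_read, byrow = TRUE) * exp(1i * phi0_t)
  }

  set.seed(seed)
  if (noise_sigma > 0) {
    nel <- length(data)
    data <- data + noise_sigma * (rnorm(nel) + 1i * rnorm(nel))
  }
  roles <- c(rep("imaging", nc), "microcoil_proximal", "microcoil_distal")
  radialKspace(data, angles_deg, times, roles, params)
}
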