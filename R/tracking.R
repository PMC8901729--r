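#' @include AllClasses.R raw_io.R
NULL

#' Projection profile of one micro-coil spoke
#'
#' Centred inverse Fourier transform magnitude of a single spoke of one
#' micro-coil channel: the catheter coil's highly localised sensitivity makes
#' this a near-zero profile with one (or two close) peaks at the coil's
#' projected position.  Readout positions are mapped to mm through the FoV
#' (the profile spans `oversampling x FoV`).
#'
#' @param spoke complex vector of one spoke's samples.
#' @param angle_deg the spoke's projection angle.
#' @param params an [AcquisitionParams-class].
#' @param spoke_index optional index for bookkeeping.
#' @return a [CoilProfile-class]; all-zero input yields a zero profile with
#'   the invalid-peak flag set.
#' @export
coilProfile <- function(spoke, angle_deg, params, spoke_index = NA_integer_) {
  n <- length(spoke)
  stopifnot(n == params@n_readout)
  prof <- abs(profileTransform(matrix(spoke, n, 1)))[, 1]
  pos <- profilePositions(params)
  valid <- max(prof) > 0
  new("CoilProfile", profile = prof, positions_mm = pos,
      angle_deg = as.numeric(angle_deg), spoke_index = as.integer(spoke_index),
      peak_mm = NA_real_, peak_intensity = NA_real_, valid = valid)
}

# centred 1D inverse DFT of each column
profileTransform <- function(spokes_mat) {
  n <- nrow(spokes_mat)
  sh <- c((n %/% 2 + 1):n, 1:(n %/% 2))
  p <- mvfft(spokes_mat[sh, , drop = FALSE], inverse = TRUE) / n
  p[sh, , drop = FALSE]
}

profilePositions <- function(params) {
  n <- params@n_readout
  (seq_len(n) - 1 - n / 2) * params@fov_mm / params@matrix_size
}

#' Smooth a projection profile and locate its peak
#'
#' Gaussian-smooths the magnitude profile, then returns the
#' intensity-weighted barycentre over the contiguous region above half the
#' smoothed maximum — robust to split peaks — and the smoothed maximum as the
#' peak intensity.
#'
#' @param profile a [CoilProfile-class].
#' @param sigma_mm Gaussian smoothing width in mm (default two native
#'   pixels).
#' @return the input profile with `peak_mm`, `peak_intensity` and `valid`
#'   filled in.
#' @export
smoothAndLocate <- function(profile, sigma_mm = NULL) {
  pos <- profile@positions_mm
  px <- pos[2] - pos[1]
  if (is.null(sigma_mm)) sigma_mm <- 2 * px
  loc <- locatePeak(gaussSmooth(profile@profile, sigma_mm / px), pos)
  if (!profile@valid || !loc$valid) {
    profile@valid <- FALSE
    return(profile)
  }
  profile@peak_mm <- loc$peak_mm
  profile@peak_intensity <- loc$intensity
  profile@valid <- TRUE
  profile
}

# Barycentre of the contiguous above-half-maximum region of a smoothed
# profile, refined by a log-parabolic apex fit (exact for the Gaussian
# micro-coil footprint; skipped when the local curvature is not concave or
# disagrees with the barycentre by more than two pixels, e.g. wide split
# peaks).
locatePeak <- function(sm, pos) {
  mx <- max(sm)
  if (!is.finite(mx) || mx <= 0 || mx - min(sm) <= 1e-12 * mx ||
      mx < 3 * median(sm))   # no peak clearly above the noise floor
    return(list(peak_mm = NA_real_, intensity = NA_real_, valid = FALSE))
  px <- pos[2] - pos[1]
  imax <- which.max(sm)
  above <- sm >= mx / 2
  lo <- imax; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- imax; while (hi < length(sm) && above[hi + 1]) hi <- hi + 1
  sel <- lo:hi
  peak <- sum(pos[sel] * sm[sel]) / sum(sm[sel])
  j0 <- min(max(round((peak - pos[1]) / px) + 1L, 2L), length(sm) - 1L)
  y <- sm[(j0 - 1L):(j0 + 1L)]
  if (all(y > 0)) {
    ly <- log(y)
    denom <- ly[1] - 2 * ly[2] + ly[3]
    if (denom < -1e-12) {
      delta <- 0.5 * (ly[1] - ly[3]) / denom
      apex <- pos[j0] + delta * px
      if (abs(delta) <= 1 && abs(apex - peak) <= 2 * px) peak <- apex
    }
  }
  list(peak_mm = peak, intensity = mx, valid = TRUE)
}

gaussSmooth <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  n <- length(x)
  K <- min(max(1L, ceiling(4 * sigma_px)), n - 1L)  # short signals: clamp
  if (K < 1L) return(x)
  kern <- exp(-((-K:K)^2) / (2 * sigma_px^2))
  kern <- kern / sum(kern)
  xp <- c(rev(x[seq_len(K)]), x, rev(x[n - seq_len(K) + 1]))  # reflect edges
  as.numeric(stats::filter(xp, kern, sides = 2))[(K + 1):(K + n)]
}

#' Localise a point source from two projections
#'
#' Solves the 2 x 2 system `p_j = x cos(rho_j) + y sin(rho_j)` — the exact
#' algebraic equivalent of locating the intersection of the two
#' back-projected ridges of a two-projection Radon map.  Near-parallel
#' projections are rejected as invalid.
#'
#' @param p1,p2 projected peak positions, mm.
#' @param rho1_deg,rho2_deg the two projection angles, degrees.
#' @param min_sin minimal `|sin(rho2 - rho1)|` accepted (conditioning guard).
#' @return list with `x_mm`, `y_mm`, `valid`.
#' @export
localizePair <- function(p1, p2, rho1_deg, rho2_deg, min_sin = 0.15) {
  r1 <- rho1_deg * pi / 180; r2 <- rho2_deg * pi / 180
  det <- sin(r2 - r1)   # determinant of the 2x2 projection matrix
  if (!is.finite(p1) || !is.finite(p2) || abs(det) < min_sin)
    return(list(x_mm = NA_real_, y_mm = NA_real_, valid = FALSE))
  x <- (p1 * sin(r2) - p2 * sin(r1)) / det
  y <- (p2 * cos(r1) - p1 * cos(r2)) / det
  list(x_mm = x, y_mm = y, valid = TRUE)
}

#' Two-projection back-projection map (diagnostic)
#'
#' Renders the product of the two back-projected smoothed profiles on a
#' coarse image grid; its intensity maximum marks the coil position and
#' agrees with the algebraic [localizePair()] solution within a pixel.
#'
#' @param prof1,prof2 smoothed [CoilProfile-class] objects.
#' @param n_grid output grid size.
#' @param fov_mm field of view of the map.
#' @return list with the map matrix, its axes in mm, and the argmax position.
#' @export
radonSpotMap <- function(prof1, prof2, n_grid = 128L, fov_mm = NULL) {
  if (is.null(fov_mm)) fov_mm <- diff(range(prof1@positions_mm)) / 2
  ax <- (seq_len(n_grid) - 1 - n_grid / 2) * fov_mm / n_grid
  X <- outer(ax, rep(1, n_grid)); Y <- outer(rep(1, n_grid), ax)
  bp <- function(prof, X, Y) {
    r <- prof@angle_deg * pi / 180
    u <- X * cos(r) + Y * sin(r)
    approx(prof@positions_mm, prof@profile, xout = u, rule = 2)$y
  }
  map <- matrix(bp(prof1, X, Y) * bp(prof2, X, Y), n_grid, n_grid)
  am <- arrayInd(which.max(map), dim(map))
  list(map = map, axes_mm = ax, argmax_mm = c(ax[am[1]], ax[am[2]]))
}

#' Remove the projection-angle-dependent position bias
#'
#' The two-projection localisation is slightly biased by the projection
#' angle; this fits a smooth periodic function of the first projection angle
#' (low-order Fourier series in the angle modulo 360) over the learning span
#' and subtracts it from the whole trace.
#'
#' @param trace a raw [MotionTrace-class].
#' @param angles_deg first-spoke projection angle of each pair.
#' @param learn_idx trace samples used for the fit (default: all).
#' @param order Fourier order of the fit.
#' @return the debiased raw [MotionTrace-class].
#' @export
debiasPositions <- function(trace, angles_deg, learn_idx = NULL, order = 4L) {
  n <- length(trace@times_s)
  stopifnot(length(angles_deg) == n)
  if (is.null(learn_idx)) learn_idx <- seq_len(n)
  if (length(learn_idx) < 4 * order + 4) {
    warning("insufficient angular coverage for the angle-bias fit; trace unchanged")
    return(trace)
  }
  th <- (angles_deg %% 360) * pi / 180
  Xd <- cbind(1, do.call(cbind, lapply(seq_len(order), function(k)
    cbind(cos(k * th), sin(k * th)))))
  for (field in c("x_mm", "y_mm")) {
    v <- slot(trace, field)
    fit <- lm.fit(Xd[learn_idx, , drop = FALSE], v[learn_idx])
    pred <- as.vector(Xd %*% fit$coefficients)
    slot(trace, field) <- v - pred + mean(v[learn_idx])
  }
  trace
}

#' Zero-phase Gaussian low-pass filter
#'
#' Symmetric Gaussian convolution whose amplitude frequency response is
#' `1/sqrt(2)` (-3 dB) at `cutoff_hz`; edges are handled by reflection.
#' Used with cutoffs of 0.883 Hz (spike removal) and 0.377 Hz (respiratory
#' extraction) on motion curves sampled every two repetition times.
#'
#' @param x numeric signal, uniformly sampled.
#' @param cutoff_hz -3 dB cutoff frequency.
#' @param sample_rate_hz sampling rate.
#' @return the filtered signal.
#' @export
gaussianLowpass <- function(x, cutoff_hz, sample_rate_hz) {
  if (cutoff_hz >= sample_rate_hz / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist rate")
  sigma_f <- cutoff_hz / sqrt(log(2))
  sigma_t <- 1 / (2 * pi * sigma_f)
  gaussSmooth(x, sigma_t * sample_rate_hz)
}

#' Decompose a motion trace into filtered, respiratory and cardiac parts
#'
#' `filtered` is the trace low-passed at 0.883 Hz (spike removal);
#' `respiratory` the trace low-passed at 0.377 Hz; `cardiac` their
#' difference.  In-plane components are mean-centred.
#'
#' @param trace a debiased raw [MotionTrace-class].
#' @param medium_hz,low_hz the two Gaussian cutoffs.
#' @return named list of [MotionTrace-class] objects
#'   (`filtered`, `respiratory`, `cardiac`).
#' @export
decomposeMotion <- function(trace, medium_hz = 0.883, low_hz = 0.377) {
  fs <- 1 / (2 * trace@tr_s)
  out <- list()
  filt <- trace; resp <- trace
  for (field in c("x_mm", "y_mm", "z_intensity")) {
    v <- slot(trace, field)
    vf <- gaussianLowpass(v, medium_hz, fs)
    vr <- gaussianLowpass(v, low_hz, fs)
    if (field != "z_intensity") {
      vf <- vf - mean(vf); vr <- vr - mean(vr)
    }
    slot(filt, field) <- vf
    slot(resp, field) <- vr
  }
  card <- filt
  card@x_mm <- filt@x_mm - resp@x_mm
  card@y_mm <- filt@y_mm - resp@y_mm
  card@z_intensity <- filt@z_intensity - resp@z_intensity
  filt@variant <- "filtered"; resp@variant <- "respiratory"; card@variant <- "cardiac"
  list(filtered = filt, respiratory = resp, cardiac = card)
}

#' Track the catheter micro-coils through an acquisition
#'
#' For every pair of consecutive spokes (temporal resolution two TR,
#' 48.28 ms at TR 24.14 ms) each requested micro-coil is localised from its
#' two smoothed projection profiles; positions are averaged over the
#' requested coils and the mean smoothed peak intensity is recorded as the
#' qualitative out-of-plane ("Z intensity") surrogate.  Invalid pairs
#' (near-parallel projections or flat profiles) are linearly interpolated in
#' time, the angle-dependent bias is removed with [debiasPositions()], and
#' the trace is decomposed with [decomposeMotion()].
#'
#' @param k a [RadialKspace-class] with micro-coil channels.
#' @param use_coils `"both"`, `"proximal"` or `"distal"`.
#' @param sigma_mm profile smoothing width (default two native pixels).
#' @param learn_idx trace samples treated as the learning span for the
#'   angle-bias fit (default: the whole trace).
#' @param max_invalid_frac error threshold on the fraction of invalid pairs.
#' @return named list of [MotionTrace-class] objects:
#'   `raw`, `filtered`, `respiratory`, `cardiac`.
#' @export
trackCatheter <- function(k, use_coils = c("both", "proximal", "distal"),
                          sigma_mm = NULL, learn_idx = NULL,
                          max_invalid_frac = 0.2) {
  use_coils <- match.arg(use_coils)
  roles <- channelRoles(k)
  coil_ch <- switch(use_coils,
    both = which(roles %in% c("microcoil_proximal", "microcoil_distal")),
    proximal = which(roles == "microcoil_proximal"),
    distal = which(roles == "microcoil_distal"))
  if (!length(coil_ch)) stop("no micro-coil channels present")
  n_spokes <- nSpokes(k)
  n_pairs <- n_spokes %/% 2L
  if (n_pairs < 2) stop("need at least two spoke pairs")
  params <- acqParams(k)
  pos <- profilePositions(params)
  px <- pos[2] - pos[1]
  if (is.null(sigma_mm)) sigma_mm <- 2 * px

  ang <- spokeAngles(k)
  xs <- ys <- zs <- rep(NA_real_, n_pairs)
  valid <- rep(FALSE, n_pairs)
  per_coil <- vector("list", length(coil_ch))
  for (ci in seq_along(coil_ch)) {
    prof_all <- abs(profileTransform(t(k@data[, , coil_ch[ci]])))
    peaks <- rep(NA_real_, n_spokes); ints <- rep(NA_real_, n_spokes)
    for (m in seq_len(n_spokes)) {
      loc <- locatePeak(gaussSmooth(prof_all[, m], sigma_mm / px), pos)
      if (loc$valid) { peaks[m] <- loc$peak_mm; ints[m] <- loc$intensity }
    }
    per_coil[[ci]] <- list(peaks = peaks, ints = ints)
  }
  for (pr in seq_len(n_pairs)) {
    i1 <- 2L * pr - 1L; i2 <- 2L * pr
    xacc <- yacc <- zacc <- 0; nok <- 0L
    for (ci in seq_along(coil_ch)) {
      pc <- per_coil[[ci]]
      loc <- localizePair(pc$peaks[i1], pc$peaks[i2], ang[i1], ang[i2])
      if (loc$valid) {
        xacc <- xacc + loc$x_mm; yacc <- yacc + loc$y_mm
        zacc <- zacc + (pc$ints[i1] + pc$ints[i2]) / 2
        nok <- nok + 1L
      }
    }
    if (nok == length(coil_ch)) {
      xs[pr] <- xacc / nok; ys[pr] <- yacc / nok; zs[pr] <- zacc / nok
      valid[pr] <- TRUE
    }
  }
  if (mean(!valid) > max_invalid_frac)
    stop(round(100 * mean(!valid)), "% of spoke pairs could not be localised; ",
         "check the slice position and the micro-coil channel flags")
  times <- (k@times_s[2 * seq_len(n_pairs) - 1] + k@times_s[2 * seq_len(n_pairs)]) / 2
  interpNA <- function(v) {
    if (all(is.na(v))) return(v)
    if (anyNA(v)) approx(times[!is.na(v)], v[!is.na(v)], xout = times, rule = 2)$y
    else v
  }
  raw <- new("MotionTrace", times_s = times, x_mm = interpNA(xs),
             y_mm = interpNA(ys), z_intensity = interpNA(zs),
             valid = valid, variant = "raw", tr_s = params@tr_s)
  pair_angles <- ang[2 * seq_len(n_pairs) - 1]
  learn_pairs <- if (is.null(learn_idx)) NULL else
    intersect(seq_len(n_pairs), unique(ceiling(learn_idx / 2)))
  raw <- debiasPositions(raw, pair_angles, learn_pairs)
  c(list(raw = raw), decomposeMotion(raw))
}

#' Select projections acquired during slow Z-intensity variation
#'
#' Computes the smoothed absolute temporal derivative of the micro-coil
#' Z-intensity and keeps the fraction of spoke pairs with the smallest
#' values, discarding projections acquired during fast out-of-plane motion
#' (ties keep the earliest samples).
#'
#' @param z_trace Z-intensity vector (one sample per spoke pair) or a
#'   [MotionTrace-class].
#' @param keep_fraction fraction of pairs to keep, in (0, 1].
#' @param sample_rate_hz sampling rate of the z trace (ignored when a trace
#'   object is given).
#' @param smooth_hz Gaussian cutoff used to smooth the derivative.
#' @return logical mask per spoke (both spokes of a pair share the value).
#' @export
selectProjections <- function(z_trace, keep_fraction = 0.70,
                              sample_rate_hz = NULL, smooth_hz = 2) {
  if (is(z_trace, "MotionTrace")) {
    sample_rate_hz <- 1 / (2 * z_trace@tr_s)
    z <- z_trace@z_intensity
  } else z <- as.numeric(z_trace)
  if (!is.finite(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  stopifnot(all(is.finite(z)))
  n <- length(z)
  dz <- c(diff(z), 0) * (sample_rate_hz %||% 1)
  if (!is.null(sample_rate_hz) && smooth_hz < sample_rate_hz / 2)
    dz <- gaussianLowpass(dz, smooth_hz, sample_rate_hz)
  score <- abs(dz)
  keep_n <- ceiling(keep_fraction * n)
  keep_pairs <- rep(FALSE, n)
  keep_pairs[order(score, seq_len(n))[seq_len(keep_n)]] <- TRUE
  rep(keep_pairs, each = 2L)
}
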