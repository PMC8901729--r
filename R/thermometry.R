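#' @include AllClasses.R recon.R library.R simulate.R
NULL

#' Construct a temperature-fit configuration
#'
#' Regularisation defaults follow the per-resolution settings that keep
#' temperature curves superimposable across temporal resolutions:
#' `lambda = 0.1, 0.2, 0.5` at 1, 2 and 3 mm with `beta = 0.05` throughout.
#' Both weights act on the normalised (unit-spectral-norm) forward operator,
#' with the temperature phase in radians.
#'
#' @param resolution_mm working in-plane resolution used to pick the default
#'   `lambda` (nearest of 1, 2, 3 mm).
#' @param window_spokes spokes per temperature frame (20, 30 or 40 give
#'   frame spacings of 0.48, 0.72 and 0.97 s at TR 24.14 ms).
#' @param stride_spokes frame advance (default: the window — non-overlapping
#'   frames reproducing those frame rates).
#' @param lambda,beta explicit regularisation weights (override defaults).
#' @param max_outer,tol,inner_theta optimisation controls.
#' @param theta_sign_constraint constrain the phase so heating is
#'   non-negative under the PRF sign convention.
#' @return a [FitConfig-class].
#' @export
fitConfig <- function(resolution_mm = 3, window_spokes = 40L,
                      stride_spokes = window_spokes, lambda = NULL,
                      beta = 0.05, max_outer = 15L, tol = 1e-3,
                      inner_theta = 5L, theta_sign_constraint = TRUE) {
  if (is.null(lambda)) {
    lut <- c(`1` = 0.1, `2` = 0.2, `3` = 0.5)
    lambda <- lut[[as.character(max(1, min(3, round(resolution_mm))))]]
  }
  new("FitConfig", lambda_sparsity = lambda, beta_roughness = beta,
      window_spokes = as.integer(window_spokes),
      stride_spokes = as.integer(stride_spokes),
      max_outer = as.integer(max_outer), tol = tol,
      inner_theta = as.integer(inner_theta),
      theta_sign_constraint = theta_sign_constraint)
}

weightedSpectralNorm <- function(plan, sqw, n_iter = 10L) {
  N <- plan$N
  set.seed(7L)
  x <- matrix(rnorm(N * N) + 1i * rnorm(N * N), N, N)
  x <- x / sqrt(sum(abs(x)^2))
  lam <- 1
  for (it in seq_len(n_iter)) {
    y <- nufftAdjointRaw(sqw * (sqw * nufftForward(x, plan)), plan)
    lam <- sqrt(sum(abs(y)^2))
    x <- y / lam
  }
  sqrt(lam)
}

applyRoughness <- function(theta) {
  # (Dxx^T Dxx + Dyy^T Dyy) theta for the second-order finite differences;
  # exact away from the outermost rows/columns, which lie outside the fit mask
  d2 <- function(m) {
    n1 <- nrow(m)
    dm <- matrix(0, n1, ncol(m))
    if (n1 >= 3) dm[2:(n1 - 1), ] <- m[1:(n1 - 2), ] - 2 * m[2:(n1 - 1), ] + m[3:n1, ]
    dm
  }
  d2(d2(theta)) + t(d2(d2(t(theta))))
}

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Voxels eligible for the polynomial (drift) fit: when the current theta
# support is compact (a hotspot), it is dilated and excluded so the smooth
# background cannot absorb the heating; when theta holds a global phase
# (e.g. drift early in the alternation) nothing is excluded and the
# polynomial is allowed to take it over.
selExcludeHeating <- function(theta_vec, mask, N, thresh = 0.05,
                              dilate_px = 3L, max_support_frac = 0.35) {
  supp <- abs(theta_vec) > max(thresh, 0.25 * max(abs(theta_vec)))
  if (!any(supp) || mean(supp[mask]) > max_support_frac) return(mask)
  sm <- matrix(supp, N, N)
  dil <- sm
  for (dx in -dilate_px:dilate_px) for (dy in -dilate_px:dilate_px) {
    if (dx == 0 && dy == 0) next
    sr <- max(1, 1 + dx):min(N, N + dx)
    tr <- max(1, 1 - dx):min(N, N - dx)
    sc <- max(1, 1 + dy):min(N, N + dy)
    tc <- max(1, 1 - dy):min(N, N - dy)
    dil[tr, tc] <- dil[tr, tc] | sm[sr, sc]
  }
  mask & !as.vector(dil)
}

libChanImages <- function(library) {
  d <- dim(library@images)
  lapply(seq_len(d[4]), function(ci) {
    matrix(library@images[, , , ci], d[1] * d[2], d[3])
  })
}

wlsPhaseFit <- function(phase, weights, A, sel) {
  ws <- weights * sel
  keep <- ws > 0
  if (sum(keep) < 2 * ncol(A)) return(rep(0, ncol(A)))
  Aw <- A[keep, , drop = FALSE] * ws[keep]
  M <- crossprod(A[keep, , drop = FALSE] * sqrt(ws[keep]))
  tryCatch(as.vector(solve(M + 1e-10 * mean(diag(M)) * diag(ncol(A)),
                           crossprod(Aw, phase[keep]))),
           error = function(e) rep(0, ncol(A)))
}

#' Image-domain hybrid multibaseline/referenceless fit (reference path)
#'
#' Fits the image-voxel model
#' `y_j = (sum_b x_bj w_b) exp(i((Ac)_j + theta_j)) + noise`
#' on a fully sampled frame image by brute-force alternation: non-negative
#' least squares for the baseline weights `w`, weighted polynomial phase
#' regression for `c` (excluding voxels currently attributed to heating),
#' and the voxelwise phase residual for `theta`.  Serves as the independent
#' oracle for [kspaceFit()] on fully sampled data.
#'
#' @param img complex image (`N x N`) or array (`N x N x n_channels`)
#'   matching the library's channels.
#' @param library a [BaselineLibrary-class].
#' @param basis a [PolynomialBasis-class] at the same matrix size.
#' @param max_iter alternation sweeps.
#' @param theta_thresh voxels with `|theta|` above this (radians) are
#'   excluded from the polynomial (drift) fit so the background does not
#'   absorb the hotspot.
#' @param sign_constraint restrict theta to the heating sign (`0` = none,
#'   `-1` / `+1` force that sign).
#' @return list with `w`, `c`, `theta` (matrix), `mask`.
#' @export
imageDomainFit <- function(img, library, basis, max_iter = 12L,
                           theta_thresh = 0.1, sign_constraint = 0) {
  N <- library@matrix_size
  B <- libChanImages(library)
  n_chan <- length(B)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  stopifnot(dim(img)[3] == n_chan, dim(img)[1] == N)
  if (all(vapply(B, function(b) max(abs(b)), 0) == 0))
    stop("library images are all zero")
  y <- lapply(seq_len(n_chan), function(ci) as.vector(img[, , ci]))
  A <- basis@basis
  nb <- ncol(B[[1]])
  magB <- sqrt(Reduce(`+`, lapply(B, function(b) rowMeans(abs(b))^2)))
  mask <- as.vector(basis@mask) & magB > 0.12 * max(magB)

  w <- rep(1 / nb, nb)
  cc <- rep(0, ncol(A))
  theta <- rep(0, N * N)
  for (it in seq_len(max_iter)) {
    bw <- lapply(B, function(b) as.vector(b %*% w))
    # total residual phase (vs the weighted baseline), channel-combined
    cross <- Reduce(`+`, lapply(seq_len(n_chan), function(ci)
      Conj(bw[[ci]]) * y[[ci]]))
    wt <- abs(cross)
    # wrapped residual after the current polynomial phase; fitting the
    # (bounded) residual incrementally avoids phase-wrap runaways that
    # fitting the raw wrapped phase directly is prone to
    delta <- Arg(cross * exp(-1i * as.vector(A %*% cc)))
    theta_new <- delta
    theta_new[!mask] <- 0
    if (sign_constraint > 0) theta_new <- pmax(theta_new, 0)
    if (sign_constraint < 0) theta_new <- pmin(theta_new, 0)
    # polynomial update from voxels not attributed to heating
    sel <- selExcludeHeating(theta_new, mask, N, theta_thresh)
    cc <- cc + as.vector(wlsPhaseFit(delta, wt, A, sel))
    theta <- Arg(cross * exp(-1i * as.vector(A %*% cc)))
    theta[!mask] <- 0
    if (sign_constraint > 0) theta <- pmax(theta, 0)
    if (sign_constraint < 0) theta <- pmin(theta, 0)
    # baseline weights given the phase
    P <- exp(1i * (as.vector(A %*% cc) + theta))
    G <- do.call(rbind, lapply(seq_len(n_chan), function(ci) B[[ci]] * P))
    yv <- unlist(y)
    Gri <- rbind(Re(G), Im(G))
    yri <- c(Re(yv), Im(yv))
    w_new <- tryCatch(pracma::lsqnonneg(Gri, yri)$x,
                      error = function(e) w)
    if (sum(w_new) > 0) w <- w_new
  }
  # final deterministic re-partition between the polynomial and theta,
  # identical in form to the unregularised k-space fit's, so the two paths
  # split the smooth phase the same way
  phi_tot <- as.vector(A %*% cc) + theta
  wt_m <- Reduce(`+`, lapply(B, function(b) abs(as.vector(b %*% w))))
  sel <- selExcludeHeating(theta, mask, N, theta_thresh)
  cc <- as.vector(wlsPhaseFit(phi_tot, wt_m, A, sel))
  theta <- phi_tot - as.vector(A %*% cc)
  theta[!mask] <- 0
  list(w = w, c = cc, theta = matrix(theta, N, N),
       mask = matrix(mask, N, N))
}

#' Direct k-space temperature fit on an undersampled window
#'
#' Fits the constrained model directly to the undersampled k-space samples of
#' one frame window, with no intermediate image reconstruction:
#' minimise `sum_ch ||y - E[(B w) exp(i(Ac + theta))]||^2 + lambda ||theta||_1
#' + beta theta' D'D theta`, where `E` is the NUFFT forward operator at the
#' window's spoke angles, `B` the baseline library stack, `A` the polynomial
#' basis and `D` the second-order finite-difference operator along both axes.
#' Solved by block alternation: non-negative linear solve for `w`,
#' damped Gauss-Newton on the polynomial phase `c` (heated voxels masked out
#' of this step through the current theta support), and proximal-gradient
#' (soft-thresholding) steps on `theta`, iterated to tolerance.  The operator
#' is normalised to unit spectral norm and the data to the library magnitude
#' scale, so `lambda` and `beta` transfer across scenes; theta is optionally
#' sign-constrained so heating is non-negative under the PRF convention.
#'
#' @param spokes complex array `n_readout x n_window x n_channels` of
#'   motion-corrected imaging-channel samples.
#' @param traj the window's [Trajectory-class] (at the working matrix size).
#' @param library a [BaselineLibrary-class] at the working matrix size.
#' @param basis a [PolynomialBasis-class].
#' @param config a [FitConfig-class].
#' @param params an [AcquisitionParams-class] (sign of the PRF constant).
#' @param init optional warm start: list with `w`, `c`, `theta` from a
#'   previous frame.  Default initialisation reconstructs the window by
#'   density-compensated adjoint and runs [imageDomainFit()] on it.
#' @param plan,op_norm optional precomputed [nufftPlan()] and spectral norm
#'   (reused across frames of a series).
#' @return list with `w`, `c`, `theta`, `converged`, `iterations`.
#' @export
kspaceFit <- function(spokes, traj, library, basis, config = fitConfig(),
                      params, init = NULL, plan = NULL, op_norm = NULL) {
  N <- library@matrix_size
  if (length(dim(spokes)) == 2L) spokes <- array(spokes, c(dim(spokes), 1L))
  n_chan <- dim(spokes)[3]
  B <- libChanImages(library)
  stopifnot(length(B) == n_chan)
  if (is.null(plan)) plan <- nufftPlan(traj, N)
  # density-weighted data fidelity: the ramp weights precondition the radial
  # normal operator to (near) identity, so the proximal steps are effective
  # and the regularisation weights act on a well-scaled residual
  sqw <- sqrt(densityCompensation(traj, N))
  if (is.null(op_norm)) op_norm <- weightedSpectralNorm(plan, sqw)
  A <- basis@basis
  nb <- ncol(B[[1]])
  magB <- sqrt(Reduce(`+`, lapply(B, function(b) rowMeans(abs(b))^2)))
  mask <- as.vector(basis@mask) & magB > 0.12 * max(magB)
  # the 1/sqrt(100) factor fixes the data-fidelity scale on which the
  # lambda/beta values act (see the methods vignette)
  sB <- sqrt(mean(magB[mask]^2)) / sqrt(100)
  Bn <- lapply(B, function(b) b / sB)
  yn <- lapply(seq_len(n_chan), function(ci) sqw * spokes[, , ci] / (op_norm * sB))
  fwd <- function(vimg) sqw * nufftForward(matrix(vimg, N, N), plan) / op_norm
  adj <- function(sp) as.vector(nufftAdjointRaw(sqw * sp, plan)) / op_norm

  sgn <- if (!config@theta_sign_constraint) 0 else
    if (prfRadPerDegC(params) < 0) -1 else 1

  if (is.null(init)) {
    # iterative inversion is only stable when the window is (near) fully
    # sampled; undersampled windows start from the plain gridded adjoint
    inv_iter <- if (plan$n_spokes >= 0.8 * pi / 2 * N) 4L else 0L
    img0 <- array(0i, c(N, N, n_chan))
    for (ci in seq_len(n_chan))
      img0[, , ci] <- nufftInverse(spokes[, , ci], plan, n_iter = inv_iter)
    init <- imageDomainFit(img0, library, basis, max_iter = 8L,
                           sign_constraint = sgn)
  }
  w <- pmax(init$w, 0); if (sum(w) == 0) w <- rep(1 / nb, nb)
  cc <- init$c
  theta <- as.vector(init$theta)
  theta[!mask] <- 0

  lam <- config@lambda_sparsity
  bet <- config@beta_roughness
  converged <- FALSE
  it_done <- 0L

  modelImgs <- function(w, cc, theta) {
    P <- exp(1i * (as.vector(A %*% cc) + theta))
    lapply(Bn, function(b) as.vector(b %*% w) * P)
  }

  for (it in seq_len(config@max_outer)) {
    theta_old <- theta
    # --- w: non-negative linear solve at fixed phase
    P <- exp(1i * (as.vector(A %*% cc) + theta))
    G <- matrix(0i, plan$n_samp * n_chan, nb)
    for (b in seq_len(nb)) {
      col <- numeric(0)
      for (ci in seq_len(n_chan))
        col <- c(col, as.vector(fwd(Bn[[ci]][, b] * P)))
      G[, b] <- col
    }
    yv <- unlist(lapply(yn, as.vector))
    Gri <- rbind(Re(G), Im(G)); yri <- c(Re(yv), Im(yv))
    w_new <- tryCatch(pracma::lsqnonneg(Gri, yri)$x, error = function(e) w)
    if (sum(w_new) > 0) w <- w_new

    # --- theta: proximal gradient with soft-thresholding
    for (inner in seq_len(config@inner_theta)) {
      M <- modelImgs(w, cc, theta)
      grad <- numeric(N * N)
      mmax <- 0
      for (ci in seq_len(n_chan)) {
        r <- fwd(M[[ci]]) - yn[[ci]]
        grad <- grad + 2 * Im(Conj(M[[ci]]) * adj(r))
        mmax <- max(mmax, max(abs(M[[ci]])))
      }
      grad <- grad + 2 * bet * as.vector(applyRoughness(matrix(theta, N, N)))
      L <- 2 * n_chan * mmax^2 + 64 * bet + 1e-6
      eta <- 0.9 / L
      theta <- softThreshold(theta - eta * grad, eta * lam)
      if (sgn > 0) theta <- pmax(theta, 0)
      if (sgn < 0) theta <- pmin(theta, 0)
      theta[!mask] <- 0
    }

    # --- c: damped Gauss-Newton on the polynomial phase, heating masked out,
    # with backtracking so a bad linearisation cannot run away
    sel <- selExcludeHeating(theta, mask, N)
    M <- modelImgs(w, cc, theta)
    K <- ncol(A)
    H <- matrix(0, K, K); gvec <- numeric(K)
    obj0 <- 0
    for (ci in seq_len(n_chan)) {
      base <- 1i * M[[ci]] * sel
      J <- matrix(0i, plan$n_samp, K)
      for (kcol in seq_len(K)) J[, kcol] <- as.vector(fwd(base * A[, kcol]))
      r <- as.vector(fwd(M[[ci]])) - as.vector(yn[[ci]])
      obj0 <- obj0 + sum(abs(r)^2)
      H <- H + Re(Conj(t(J)) %*% J)
      gvec <- gvec + Re(as.vector(Conj(t(J)) %*% r))
    }
    dc <- tryCatch(-solve(H + 1e-9 * diag(K), gvec), error = function(e) rep(0, K))
    step <- 1
    for (bt in 1:4) {
      cand <- cc + step * dc
      Mc <- modelImgs(w, cand, theta)
      objc <- sum(vapply(seq_len(n_chan), function(ci)
        sum(abs(as.vector(fwd(Mc[[ci]])) - as.vector(yn[[ci]]))^2), 0))
      if (objc <= obj0) { cc <- cand; break }
      step <- step / 4
    }

    it_done <- it
    if (max(abs(theta - theta_old)) < config@tol) { converged <- TRUE; break }
  }

  # with no sparsity penalty the split between Ac and theta is degenerate;
  # re-partition so theta is the residual after the masked polynomial fit
  if (lam == 0) {
    phi <- as.vector(A %*% cc) + theta
    wt <- Reduce(`+`, lapply(modelImgs(w, cc, theta), abs))
    sel <- selExcludeHeating(theta, mask, N)
    cc <- as.vector(wlsPhaseFit(phi, wt, A, sel))
    theta <- phi - as.vector(A %*% cc)
    theta[!mask] <- 0
  }

  list(w = w, c = cc, theta = matrix(theta, N, N),
       converged = converged, iterations = it_done,
       mask = matrix(mask, N, N))
}

#' Convert a PRF phase map to temperature change
#'
#' `deltaT = theta / (2 pi gamma B0 alpha 1e-6 TE)`; with the negative water
#' PRF coefficient, heating (negative phase at positive TE) maps to positive
#' temperature change.  At TE 20 ms, B0 1.5 T and |alpha| 0.01 ppm/degC a
#' phase of 0.08026 rad corresponds to 1.000 degC.
#'
#' @param theta phase map (radians) or array.
#' @param params an [AcquisitionParams-class].
#' @return temperature change map in degrees C.
#' @export
phaseToTemperature <- function(theta, params) {
  prf <- prfRadPerDegC(params)
  if (params@prf_alpha_ppm_per_degC == 0) stop("PRF coefficient alpha is zero")
  theta / prf
}

#' Run the temperature series over consecutive spoke windows
#'
#' Advances windows of `window_spokes` motion-corrected spokes by
#' `stride_spokes` (default non-overlapping, reproducing frame spacings of
#' 0.48 / 0.72 / 0.97 s for 20 / 30 / 40 spokes at TR 24.14 ms), fitting each
#' window with [kspaceFit()] (warm-started from the previous frame) and
#' converting phase to temperature.
#'
#' @param k motion-corrected [RadialKspace-class] at the working resolution
#'   (see [truncateReadout()]).
#' @param library a [BaselineLibrary-class].
#' @param basis a [PolynomialBasis-class].
#' @param config a [FitConfig-class].
#' @param start_spoke first spoke eligible for fitting (first spoke after
#'   the learning span).
#' @param end_spoke last eligible spoke (default: all).
#' @param verbose print per-frame progress.
#' @return a [TemperatureSeries-class].
#' @export
runSeries <- function(k, library, basis, config, start_spoke = 1L,
                      end_spoke = nSpokes(k), verbose = FALSE) {
  N <- library@matrix_size
  stopifnot(N == k@params@matrix_size)
  win <- config@window_spokes
  stride <- config@stride_spokes
  starts <- seq.int(start_spoke, by = stride,
                    length.out = max(0, (end_spoke - start_spoke + 1 - win) %/% stride + 1))
  if (!length(starts)) stop("window of ", win, " spokes does not fit between ",
                            start_spoke, " and ", end_spoke)
  ich <- imagingChannels(k)
  nf <- length(starts)
  theta <- array(0, c(N, N, nf))
  wmat <- matrix(0, length(binCounts(library)), nf)
  cmat <- NULL
  times <- numeric(nf)
  conv <- logical(nf)
  sidx <- vector("list", nf)
  op_norm <- NULL
  # anchor the warm-start chain on a fully sampled reference fit of the
  # spokes immediately preceding the first window (typically the end of the
  # learning span); a cold start on a single undersampled window is far less
  # reliable
  fit <- NULL
  n_ref <- as.integer(ceiling(pi / 2 * N))
  if (start_spoke - 1L >= n_ref) {
    idx0 <- (start_spoke - n_ref):(start_spoke - 1L)
    traj0 <- buildTrajectory(k@angles_deg[idx0], k@params, N)
    plan0 <- nufftPlan(traj0, N)
    img0 <- array(0i, c(N, N, length(ich)))
    for (ci in seq_along(ich))
      img0[, , ci] <- nufftInverse(t(k@data[idx0, , ich[ci]]), plan0)
    sgn0 <- if (prfRadPerDegC(k@params) < 0) -1 else 1
    fit <- imageDomainFit(img0, library, basis, sign_constraint = sgn0)
  }
  for (f in seq_len(nf)) {
    idx <- starts[f]:(starts[f] + win - 1L)
    sidx[[f]] <- as.integer(idx)
    times[f] <- mean(k@times_s[idx])
    sp <- array(0i, c(k@params@n_readout, win, length(ich)))
    for (ci in seq_along(ich)) sp[, , ci] <- t(k@data[idx, , ich[ci]])
    traj <- buildTrajectory(k@angles_deg[idx], k@params, N)
    plan <- nufftPlan(traj, N)
    if (is.null(op_norm))
      op_norm <- weightedSpectralNorm(plan, sqrt(densityCompensation(traj, N)))
    fit <- kspaceFit(sp, traj, library, basis, config, k@params,
                     init = fit, plan = plan, op_norm = op_norm)
    theta[, , f] <- fit$theta
    wmat[, f] <- fit$w
    if (is.null(cmat)) cmat <- matrix(0, length(fit$c), nf)
    cmat[, f] <- fit$c
    conv[f] <- fit$converged
    if (verbose) message("frame ", f, "/", nf, " t=", round(times[f], 2),
                         "s iters=", fit$iterations)
  }
  new("TemperatureSeries", theta = theta,
      deltaT = phaseToTemperature(theta, k@params),
      times_s = times, spoke_idx = sidx, w = wmat, c = cmat,
      converged = conv, window_spokes = win, stride_spokes = stride,
      params = k@params)
}

#' Temporally filter a temperature series
#'
#' Zero-phase (forward-backward) low-pass Butterworth filter applied per
#' voxel across frames; default cutoff 0.14 Hz, order 4.
#'
#' @param series a [TemperatureSeries-class] with uniform frame spacing.
#' @param cutoff_hz -3 dB cutoff frequency.
#' @param order Butterworth order (reduced automatically for very short
#'   series).
#' @return the filtered [TemperatureSeries-class].
#' @export
temporalFilter <- function(series, cutoff_hz = 0.14, order = 4L) {
  ts <- series@times_s
  nf <- length(ts)
  if (nf < 2) return(series)
  dt <- diff(ts)
  stopifnot(max(abs(dt - dt[1])) < 1e-6)
  fs <- 1 / dt[1]
  if (cutoff_hz >= fs / 2)
    stop("cutoff ", cutoff_hz, " Hz is at or above the frame Nyquist rate ",
         round(fs / 2, 3), " Hz")
  while (order > 1 && nf <= 3 * (order + 1)) order <- order - 1L
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-symmetric edge padding suppresses the forward-backward edge transient
  P <- min(nf - 1L, as.integer(ceiling(3 / (cutoff_hz * dt[1]))))
  ff <- function(v) {
    vp <- c(2 * v[1] - v[(P + 1):2], v, 2 * v[nf] - v[(nf - 1):(nf - P)])
    signal::filtfilt(bf, vp)[(P + 1):(P + nf)]
  }
  N <- dim(series@theta)[1]
  flat <- matrix(series@deltaT, N * N, nf)
  keep <- which(apply(flat, 1, function(v) any(v != 0)))
  for (j in keep) flat[j, ] <- ff(flat[j, ])
  series@deltaT <- array(flat, c(N, N, nf))
  series@theta <- series@deltaT * prfRadPerDegC(series@params)
  series
}

#' Background-ROI temperature uncertainty
#'
#' Per-voxel temporal standard deviation of the temperature over the frames
#' after the library training period and before heating onset, summarised as
#' mean +/- SD over the ROI voxels.
#'
#' @param series a [TemperatureSeries-class].
#' @param roi logical matrix at the series' matrix size.
#' @param training_end_s,heating_start_s evaluation span bounds (seconds).
#' @return a [RoiStats-class].
#' @export
roiUncertainty <- function(series, roi, training_end_s, heating_start_s) {
  sel <- which(series@times_s > training_end_s & series@times_s < heating_start_s)
  if (length(sel) < 2)
    stop("no frames between training end (", training_end_s,
         " s) and heating start (", heating_start_s, " s)")
  N <- dim(series@theta)[1]
  stopifnot(all(dim(roi) == c(N, N)))
  flat <- matrix(series@deltaT[, , sel], N * N, length(sel))
  sds <- apply(flat[as.vector(roi), , drop = FALSE], 1, sd)
  new("RoiStats", roi = roi, per_voxel_sd = sds,
      mean_sd = mean(sds), sd_sd = sd(sds), n_frames = length(sel))
}
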