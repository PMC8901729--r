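#' @include AllClasses.R raw_io.R
NULL

#' Estimate the imaging-channel noise covariance
#'
#' Estimates the complex noise covariance across imaging channels from the
#' outermost readout samples of all spokes (2.5 % at each readout edge — the
#' object-free, highest-spatial-frequency region), averaged over spokes.
#'
#' @param k a [RadialKspace-class].
#' @param edge_fraction total fraction of readout samples used (split
#'   between the two edges).
#' @return a [ChannelModel-class] with the covariance filled in (whitening
#'   and compression identity until [prewhitenAndCompress()] is run).
#' @export
estimateNoise <- function(k, edge_fraction = 0.05) {
  ich <- imagingChannels(k)
  if (!length(ich)) stop("no imaging channels present")
  n <- k@params@n_readout
  n_edge <- max(1L, ceiling(edge_fraction / 2 * n))
  idx <- c(seq_len(n_edge), n - seq_len(n_edge) + 1L)
  nc <- length(ich)
  X <- matrix(0i, nSpokes(k) * length(idx), nc)
  for (j in seq_along(ich)) X[, j] <- as.vector(k@data[, idx, ich[j]])
  n_samp <- nrow(X)
  if (n_samp < 1000) {
    warning("fewer than 1000 noise samples; using identity covariance")
    C <- diag(nc) + 0i
  } else {
    C <- crossprod(Conj(X), X) / n_samp
  }
  new("ChannelModel", covariance = as.matrix(C),
      whitening = diag(nc) + 0i, compression = diag(nc) + 0i,
      retained_variance = 1, n_in = as.integer(nc), n_out = as.integer(nc))
}

#' Pre-whiten and PCA-compress the imaging channels
#'
#' Whitens the imaging channels with the estimated noise covariance, then
#' projects them onto the leading principal components capturing at least
#' `variance_threshold` of the total (whitened) signal variance.  Micro-coil
#' channels pass through unchanged; angles and timestamps are untouched.
#'
#' @param k a [RadialKspace-class].
#' @param model a [ChannelModel-class] from [estimateNoise()].
#' @param variance_threshold retained-variance fraction, in (0, 1].
#' @return list with the compressed [RadialKspace-class] (`k`) and the
#'   completed [ChannelModel-class] (`model`).
#' @export
prewhitenAndCompress <- function(k, model = estimateNoise(k),
                                 variance_threshold = 0.90) {
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]")
  ich <- imagingChannels(k)
  mch <- microcoilChannels(k)
  nc <- length(ich)
  d <- dim(k@data)
  X <- matrix(0i, d[1] * d[2], nc)
  for (j in seq_along(ich)) X[, j] <- as.vector(k@data[, , ich[j]])

  C <- model@covariance
  # whitening: fall back to identity for (near-)noiseless data
  scale0 <- mean(abs(X)^2)
  W <- if (nc == 1L || mean(Re(diag(C))) < 1e-12 * max(scale0, 1e-300)) {
    diag(nc) + 0i
  } else {
    # symmetric (ZCA) whitening W = V L^{-1/2} V^H, so W^H C W = I and
    # whitening already-white data is (near) the identity
    eg <- eigen((C + Conj(t(C))) / 2)
    eg$vectors %*% diag(1 / sqrt(pmax(Re(eg$values), 1e-300)), nc) %*%
      Conj(t(eg$vectors))
  }
  Xw <- X %*% W

  # PCA on the whitened signal covariance
  Cs <- crossprod(Conj(Xw), Xw) / nrow(Xw)
  eg <- eigen((Cs + Conj(t(Cs))) / 2, symmetric = TRUE)
  ev <- pmax(Re(eg$values), 0)
  cum <- cumsum(ev) / sum(ev)
  n_keep <- if (variance_threshold >= 1) nc else which(cum >= variance_threshold)[1]
  P <- eg$vectors[, seq_len(n_keep), drop = FALSE]
  # fix the eigenvector phase so repeated application is stable
  for (j in seq_len(ncol(P))) {
    piv <- which.max(abs(P[, j]))
    ph <- P[piv, j] / abs(P[piv, j])
    P[, j] <- P[, j] / ph
  }
  Xc <- Xw %*% P

  out <- array(0i, c(d[1], d[2], n_keep + length(mch)))
  for (j in seq_len(n_keep)) out[, , j] <- matrix(Xc[, j], d[1], d[2])
  for (j in seq_along(mch)) out[, , n_keep + j] <- k@data[, , mch[j]]
  roles <- c(rep("imaging", n_keep), k@channel_roles[mch])
  model@whitening <- as.matrix(W)
  model@compression <- as.matrix(P)
  model@retained_variance <- cum[n_keep]
  model@n_out <- as.integer(n_keep)
  list(k = radialKspace(out, k@angles_deg, k@times_s, roles, k@params),
       model = model)
}

#' Apply a fitted channel model to another acquisition segment
#'
#' Applies the whitening and PCA compression of an already-fitted
#' [ChannelModel-class] (e.g. estimated on the learning phase) to the
#' imaging channels of `k`, so that later segments share the library's
#' channel definition.
#'
#' @param k a [RadialKspace-class].
#' @param model a completed [ChannelModel-class] from
#'   [prewhitenAndCompress()].
#' @return the transformed [RadialKspace-class].
#' @export
applyChannelModel <- function(k, model) {
  ich <- imagingChannels(k)
  mch <- microcoilChannels(k)
  stopifnot(length(ich) == model@n_in)
  d <- dim(k@data)
  X <- matrix(0i, d[1] * d[2], model@n_in)
  for (j in seq_along(ich)) X[, j] <- as.vector(k@data[, , ich[j]])
  Xc <- X %*% model@whitening %*% model@compression
  out <- array(0i, c(d[1], d[2], model@n_out + length(mch)))
  for (j in seq_len(model@n_out)) out[, , j] <- matrix(Xc[, j], d[1], d[2])
  for (j in seq_along(mch)) out[, , model@n_out + j] <- k@data[, , mch[j]]
  roles <- c(rep("imaging", model@n_out), k@channel_roles[mch])
  radialKspace(out, k@angles_deg, k@times_s, roles, k@params)
}

#' Motion-correct one spoke by a k-space phase ramp
#'
#' Applies the Fourier shift theorem along the spoke:
#' `out(k_r) = in(k_r) * exp(+2i pi k_r (dx cos(rho) + dy sin(rho)) / FoV)`,
#' with `k_r` in cycles per FoV and displacements in mm.  With `(dx, dy)`
#' equal to the spoke's displacement relative to the mean position, the
#' corrected spoke equals the spoke a static (mean-position) object would
#' have produced.  The per-spoke L2 norm is preserved exactly.
#'
#' @param spoke complex sample vector of one spoke.
#' @param kr radial coordinates of the samples, cycles per FoV.
#' @param angle_deg the spoke angle.
#' @param dx_mm,dy_mm displacement to remove.
#' @param fov_mm field of view, mm.
#' @return the corrected spoke; a non-finite displacement returns the spoke
#'   unchanged with attribute `flagged = TRUE`.
#' @export
correctSpoke <- function(spoke, kr, angle_deg, dx_mm, dy_mm, fov_mm) {
  if (!is.finite(dx_mm) || !is.finite(dy_mm)) {
    attr(spoke, "flagged") <- TRUE
    return(spoke)
  }
  rho <- angle_deg * pi / 180
  u <- (dx_mm * cos(rho) + dy_mm * sin(rho)) / fov_mm
  spoke * exp(2i * pi * kr * u)
}

#' Motion-correct all imaging spokes of an acquisition
#'
#' Looks up each spoke pair's displacement in the filtered motion trace
#' (both spokes of a pair get the pair's value), subtracts the mean position
#' over the learning span, and applies [correctSpoke()] to every
#' imaging-channel spoke.  Micro-coil channels are left untouched.
#'
#' @param k a [RadialKspace-class].
#' @param trace the filtered [MotionTrace-class] (one sample per spoke pair,
#'   covering the acquisition span).
#' @param learn_idx spoke indices of the learning span used for the mean
#'   position (default: the whole trace).
#' @param reference `"learning_mean"` (subtract the learning-span mean
#'   position) or `"zero"` (use the trace values as-is).
#' @return the motion-corrected [RadialKspace-class].
#' @export
correctAll <- function(k, trace, learn_idx = NULL,
                       reference = c("learning_mean", "zero")) {
  reference <- match.arg(reference)
  n_spokes <- nSpokes(k)
  n_pairs <- length(trace@times_s)
  if (2L * n_pairs < n_spokes - 1L)
    stop("motion trace (", n_pairs, " pairs) does not cover the ",
         n_spokes, "-spoke acquisition")
  pair_of <- pmin(ceiling(seq_len(n_spokes) / 2), n_pairs)
  dx <- trace@x_mm[pair_of]
  dy <- trace@y_mm[pair_of]
  if (reference == "learning_mean") {
    lp <- if (is.null(learn_idx)) seq_len(n_pairs) else
      unique(pmin(ceiling(learn_idx / 2), n_pairs))
    dx <- dx - mean(trace@x_mm[lp])
    dy <- dy - mean(trace@y_mm[lp])
  }
  p <- k@params
  kr <- (seq_len(p@n_readout) - 1 - p@n_readout / 2) * p@k_spacing_cyc_fov
  rho <- (k@angles_deg %% 360) * pi / 180
  u <- (dx * cos(rho) + dy * sin(rho)) / p@fov_mm      # per spoke
  u[!is.finite(u)] <- 0
  ramp <- exp(2i * pi * outer(u, kr))                   # spokes x readout
  out <- k@data
  for (ch in imagingChannels(k)) out[, , ch] <- out[, , ch] * ramp
  radialKspace(out, k@angles_deg, k@times_s, k@channel_roles, p)
}
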