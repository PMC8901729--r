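#' @include AllClasses.R recon.R
NULL

#' Bin learning spokes by a 1D motion curve
#'
#' Equal-count (quantile) binning of the displacement curve — the phantom
#' scheme: a library of 10 baseline images built from the X motion curve,
#' with per-bin spoke counts differing by at most one.
#'
#' @param x_curve displacement value of every learning spoke.
#' @param n_bins number of bins (default 10).
#' @return integer bin label per spoke (1-based, ordered by displacement).
#' @export
assignBins1d <- function(x_curve, n_bins = 10L) {
  stopifnot(all(is.finite(x_curve)))
  n <- length(x_curve)
  if (n_bins > n) stop("more bins (", n_bins, ") than spokes (", n, ")")
  if (diff(range(x_curve)) < 1e-9 || length(unique(x_curve)) < n_bins)
    stop("motion curve is (nearly) constant: all spokes would fall in one ",
         "bin; reduce n_bins")
  as.integer(ceiling(rank(x_curve, ties.method = "first") * n_bins / n))
}

cardiacPhase <- function(cardiac_signal, sample_rate_hz, min_rr_s = 0.4) {
  z <- cardiac_signal - mean(cardiac_signal)
  if (sd(z) < 1e-12) stop("cardiac signal has no detectable peaks; ",
                          "consider 1D binning")
  pk <- pracma::findpeaks(z, minpeakdistance = max(2, round(min_rr_s * sample_rate_hz)),
                          minpeakheight = 0.3 * max(z))
  if (is.null(pk) || nrow(pk) < 3)
    stop("cardiac signal has no detectable peaks; consider 1D binning")
  locs <- sort(pk[, 2])
  n <- length(z)
  phase <- rep(NA_real_, n)
  for (i in seq_len(length(locs) - 1)) {
    span <- locs[i]:(locs[i + 1] - 1)
    phase[span] <- (span - locs[i]) / (locs[i + 1] - locs[i])
  }
  rr <- mean(diff(locs))
  before <- seq_len(locs[1] - 1)
  if (length(before)) phase[before] <- ((before - locs[1]) %% rr) / rr
  after <- locs[length(locs)]:n
  phase[after] <- ((after - locs[length(locs)]) %% rr) / rr
  phase
}

#' Bin learning spokes by respiratory and cardiac phase
#'
#' The in-vivo scheme: respiratory label from equal-count binning of the
#' respiratory displacement (8 levels) crossed with the cardiac phase tertile
#' within each cardiac cycle (cycle boundaries from the peaks of the cardiac
#' signal), giving 24 = 3 x 8 joint bins.
#'
#' @param resp_curve respiratory displacement per learning spoke.
#' @param cardiac_signal cardiac signal per learning spoke (e.g. the cardiac
#'   motion component or the Z intensity).
#' @param n_resp,n_card respiratory and cardiac phase counts.
#' @param sample_rate_hz sampling rate of the per-spoke curves.
#' @return integer joint bin label per spoke, with attributes
#'   `resp`, `card` (the marginal labels) and `empty` (empty joint cells).
#' @export
assignBins2d <- function(resp_curve, cardiac_signal, n_resp = 8L, n_card = 3L,
                         sample_rate_hz = 1 / 0.04828) {
  stopifnot(length(resp_curve) == length(cardiac_signal))
  resp <- as.integer(ceiling(rank(resp_curve, ties.method = "first") *
                               n_resp / length(resp_curve)))
  phase <- cardiacPhase(cardiac_signal, sample_rate_hz)
  card <- pmin(as.integer(floor(phase * n_card)) + 1L, n_card)
  joint <- (resp - 1L) * n_card + card
  empty <- setdiff(seq_len(n_resp * n_card), unique(joint))
  structure(joint, resp = resp, card = card, empty = empty,
            n_bins = n_resp * n_card)
}

#' Build the motion-state multibaseline library
#'
#' Reconstructs one complex baseline image per motion-state bin (per
#' compressed imaging channel) by density-compensated adjoint gridding of
#' that bin's motion-corrected learning spokes.
#'
#' @param k motion-corrected [RadialKspace-class].
#' @param labels integer bin label per learning spoke.
#' @param learning_idx spoke indices of the learning span (default: all).
#' @param matrix_size working image matrix.
#' @param min_count minimal spokes per bin; smaller bins raise an error
#'   (or are merged into the nearest bin when `merge = TRUE`).
#' @param merge merge undersized bins instead of failing.
#' @return a [BaselineLibrary-class].
#' @export
buildLibrary <- function(k, labels, learning_idx = seq_len(nSpokes(k)),
                         matrix_size = k@params@matrix_size,
                         min_count = 20L, merge = FALSE) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(learning_idx))
  n_bins <- max(labels)
  counts <- tabulate(labels, n_bins)
  if (any(counts < min_count)) {
    if (!merge)
      stop("bin(s) ", paste(which(counts < min_count), collapse = ", "),
           " have fewer than ", min_count, " spokes; reduce the bin count ",
           "or set merge = TRUE")
    for (b in which(counts < min_count)) {
      ok <- which(counts >= min_count)
      tgt <- ok[which.min(abs(ok - b))]
      labels[labels == b] <- tgt
    }
    keep <- sort(unique(labels))
    labels <- match(labels, keep)
    n_bins <- length(keep)
    counts <- tabulate(labels, n_bins)
  }
  ich <- imagingChannels(k)
  imgs <- array(0i, c(matrix_size, matrix_size, n_bins, length(ich)))
  for (b in seq_len(n_bins)) {
    idx <- learning_idx[labels == b]
    traj <- buildTrajectory(k@angles_deg[idx], k@params, matrix_size)
    plan <- nufftPlan(traj, matrix_size)
    wdc <- densityCompensation(traj, matrix_size)
    for (ci in seq_along(ich)) {
      sp <- t(k@data[idx, , ich[ci], drop = FALSE][, , 1])
      imgs[, , b, ci] <- nufftAdjointRaw(sp * wdc, plan)
    }
  }
  new("BaselineLibrary", images = imgs,
      bins = list(scheme = if (!is.null(attr(labels, "n_bins"))) "2d" else "1d",
                  n_bins = n_bins),
      counts = as.integer(counts), labels = labels,
      learning_idx = as.integer(learning_idx),
      matrix_size = as.integer(matrix_size))
}

#' Orthonormal low-order 2D polynomial basis
#'
#' Monomials `x^p y^q` with `p + q <= order` on normalised `[-1, 1]^2` image
#' coordinates, orthonormalised (thin QR) over the given mask.  Order 6 gives
#' 28 columns — the smooth background basis that absorbs B0 drift and
#' residual motion-related phase.
#'
#' @param matrix_size image matrix size.
#' @param order maximal total order (>= 0).
#' @param mask logical matrix of voxels the basis is orthonormal over
#'   (default: the central disk inscribed in the FoV).
#' @return a [PolynomialBasis-class].
#' @export
polynomialBasis <- function(matrix_size, order = 6L, mask = NULL) {
  if (order < 0) stop("order must be non-negative")
  N <- as.integer(matrix_size)
  u <- (seq_len(N) - 1 - N / 2) / (N / 2)
  X <- outer(u, rep(1, N)); Y <- outer(rep(1, N), u)
  if (is.null(mask)) mask <- (X^2 + Y^2) <= 1
  if (!any(mask)) stop("mask is empty")
  cols <- list()
  for (tot in 0:order) for (p in tot:0) {
    cols[[length(cols) + 1L]] <- as.vector(X^p * Y^(tot - p))
  }
  P <- do.call(cbind, cols)
  qrd <- qr(P[as.vector(mask), , drop = FALSE])
  if (qrd$rank < ncol(P))
    stop("mask too small to support a degree-", order, " basis")
  Rm <- qr.R(qrd)
  basis <- P %*% backsolve(Rm, diag(ncol(P)))
  new("PolynomialBasis", basis = basis, order = as.integer(order),
      mask = mask, matrix_size = N)
}
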