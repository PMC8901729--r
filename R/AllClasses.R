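#' @import methods
#' @useDynLib radialtherm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft approx coef lm.fit median quantile rnorm runif sd convolve
#' @importFrom utils head tail modifyList write.csv
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Acquisition parameters for a radial golden-angle gradient-echo scan
#'
#' Holds the geometry and timing of a 2D radial acquisition: field of view,
#' readout length and oversampling, echo/repetition times, static field and
#' the PRF thermometry constants.  The k-space sample spacing (in cycles per
#' field of view) is fixed at construction from the native matrix size and
#' readout length and is preserved when the readout is truncated to a coarser
#' resolution, so truncated data keep their physical k-space locations.
#'
#' @slot fov_mm field of view in mm.
#' @slot n_readout number of acquired samples per spoke (even).
#' @slot oversampling readout oversampling factor.
#' @slot matrix_size image matrix size the readout supports (FoV / pixel).
#' @slot k_spacing_cyc_fov spacing between readout samples, cycles per FoV.
#' @slot slice_thickness_mm slice thickness in mm.
#' @slot te_s echo time in seconds.
#' @slot tr_s repetition time in seconds.
#' @slot flip_deg flip angle in degrees.
#' @slot readout_bandwidth_hz_per_px readout bandwidth, Hz per pixel.
#' @slot b0_tesla static field strength in tesla.
#' @slot gamma_hz_per_tesla gyromagnetic ratio, Hz per tesla.
#' @slot prf_alpha_ppm_per_degC PRF thermal coefficient, ppm per degree C
#'   (negative: resonance frequency decreases on heating).
#' @export
setClass("AcquisitionParams",
  representation(
    fov_mm = "numeric",
    n_readout = "integer",
    oversampling = "numeric",
    matrix_size = "integer",
    k_spacing_cyc_fov = "numeric",
    slice_thickness_mm = "numeric",
    te_s = "numeric",
    tr_s = "numeric",
    flip_deg = "numeric",
    readout_bandwidth_hz_per_px = "numeric",
    b0_tesla = "numeric",
    gamma_hz_per_tesla = "numeric",
    prf_alpha_ppm_per_degC = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  pos <- c(fov_mm = object@fov_mm, n_readout = object@n_readout,
           oversampling = object@oversampling, matrix_size = object@matrix_size,
           te_s = object@te_s, tr_s = object@tr_s, b0 = object@b0_tesla,
           gamma = object@gamma_hz_per_tesla)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "fov, readout, oversampling, matrix, TE, TR, B0, gamma must all be positive")
  if (length(object@te_s) && length(object@tr_s) && object@te_s >= object@tr_s)
    msg <- c(msg, "te_s must be smaller than tr_s")
  if (length(object@n_readout) && object@n_readout %% 2L != 0L)
    msg <- c(msg, "n_readout must be even")
  if (length(msg)) msg else TRUE
})

#' Synthetic phantom scene
#'
#' Ground-truth description of a synthetic object used by the acquisition
#' simulator: a non-negative magnitude image, smooth complex coil
#' sensitivities, two catheter micro-coil positions, and parametric models for
#' rigid in-plane motion, the PRF heating hotspot, motion-state-dependent
#' background phase, B0 drift and complex noise.
#'
#' @slot magnitude real non-negative matrix (a.u.), `n_pix` x `n_pix`.
#' @slot sensitivities complex array `n_pix x n_pix x n_channels`.
#' @slot microcoil_positions 2 x 2 matrix of (x, y) positions in mm relative
#'   to the FoV centre; rows are proximal and distal coils.
#' @slot motion_model list describing the rigid motion (see [makeScene()]).
#' @slot hotspot_model list describing the heating hotspot.
#' @slot background_phase_model list with matrices `static` and
#'   `motion_coupled` (radians); the applied background phase is
#'   `static + s(t) * motion_coupled` with `s(t)` the displacement-scaled
#'   motion state (displacement magnitude / 20 mm).
#' @slot drift_rad_per_s spatially uniform linear phase-drift rate.
#' @slot coil_model list with the micro-coil signal model (amplitude,
#'   Gaussian footprint sigma in mm, out-of-plane attenuation sigma in mm).
#' @slot noise_sigma per-channel complex-noise standard deviation (recycled).
#' @slot fov_mm field of view in mm.
#' @slot n_pix scene grid size in pixels.
#' @slot seed integer seed that fully determines the scene.
#' @export
setClass("PhantomScene",
  representation(
    magnitude = "matrix",
    sensitivities = "array",
    microcoil_positions = "matrix",
    motion_model = "list",
    hotspot_model = "list",
    background_phase_model = "list",
    drift_rad_per_s = "numeric",
    coil_model = "list",
    noise_sigma = "numeric",
    fov_mm = "numeric",
    n_pix = "integer",
    seed = "integer"
  )
)

setValidity("PhantomScene", function(object) {
  msg <- character()
  if (any(object@magnitude < 0)) msg <- c(msg, "magnitude must be non-negative everywhere")
  if (!all(is.finite(object@magnitude))) msg <- c(msg, "magnitude must be finite")
  if (!all(is.finite(Re(object@sensitivities))) || !all(is.finite(Im(object@sensitivities))))
    msg <- c(msg, "sensitivities must be finite")
  if (any(abs(object@microcoil_positions) > object@fov_mm / 2))
    msg <- c(msg, "micro-coil positions must lie inside the FoV")
  hs <- object@hotspot_model
  if (!is.null(hs$sigma_mm) && hs$sigma_mm <= 0) msg <- c(msg, "hotspot sigma must be positive")
  if (!is.null(hs$center_mm) && any(abs(hs$center_mm) > object@fov_mm / 2))
    msg <- c(msg, "hotspot center must lie inside the FoV")
  if (length(msg)) msg else TRUE
})

#' Raw radial golden-angle k-space container
#'
#' Complex spoke samples for all receive channels together with the per-spoke
#' accumulated golden-angle, acquisition timestamps, per-channel roles and the
#' acquisition parameters.  Channels flagged `microcoil_proximal` /
#' `microcoil_distal` carry the catheter tracking signal and are excluded from
#' image reconstruction.
#'
#' @slot data complex array `n_spokes x n_readout x n_channels`.
#' @slot angles_deg accumulated golden-angle per spoke (not reduced mod 360).
#' @slot times_s acquisition time of each spoke in seconds.
#' @slot channel_roles character vector, one of `"imaging"`,
#'   `"microcoil_proximal"`, `"microcoil_distal"` per channel.
#' @slot params an [AcquisitionParams-class] object.
#' @export
setClass("RadialKspace",
  representation(
    data = "array",
    angles_deg = "numeric",
    times_s = "numeric",
    channel_roles = "character",
    params = "AcquisitionParams"
  )
)

setValidity("RadialKspace", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3D array [spokes x readout x channels]")
  else {
    if (d[1] != length(object@angles_deg)) msg <- c(msg, "angles_deg length must match spoke count")
    if (d[1] != length(object@times_s)) msg <- c(msg, "times_s length must match spoke count")
    if (d[3] != length(object@channel_roles)) msg <- c(msg, "one channel role per channel required")
    if (d[2] != object@params@n_readout)
      msg <- c(msg, "readout length must match params n_readout")
  }
  if (!all(object@channel_roles %in% c("imaging", "microcoil_proximal", "microcoil_distal")))
    msg <- c(msg, "unknown channel role")
  if (length(object@angles_deg) > 1) {
    incr <- diff(object@angles_deg)
    if (any(incr <= 0)) msg <- c(msg, "angles_deg must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Radial k-space trajectory
#'
#' Per-spoke radial sample coordinates.  `kr` holds the signed radial
#' coordinate of every readout sample in cycles per FoV (symmetric about 0,
#' containing the DC sample); each spoke's 2D sample locations are
#' `kr * (cos(rho), sin(rho))` with `rho` the spoke angle measured
#' counter-clockwise from the x axis.
#'
#' @slot kr numeric vector of radial coordinates, cycles per FoV.
#' @slot angles_deg per-spoke angle in degrees (accumulated golden angle).
#' @slot fov_mm field of view in mm.
#' @slot matrix_size target image matrix size.
#' @export
setClass("Trajectory",
  representation(
    kr = "numeric",
    angles_deg = "numeric",
    fov_mm = "numeric",
    matrix_size = "integer"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@kr) > 1) {
    dk <- diff(object@kr)
    if (max(abs(dk - dk[1])) > 1e-9) msg <- c(msg, "kr spacing must be uniform")
  }
  if (max(abs(object@kr)) > object@matrix_size / 2 + 1e-9)
    msg <- c(msg, "|kr| must not exceed matrix_size/2")
  if (length(msg)) msg else TRUE
})

#' Magnitude profile of one spoke (projection)
#'
#' The centred inverse Fourier transform magnitude of a single spoke of one
#' micro-coil channel, with readout positions mapped to mm, and the located
#' peak (position and intensity) if valid.
#'
#' @slot profile non-negative magnitude profile along the projection.
#' @slot positions_mm readout position of each profile sample, mm.
#' @slot angle_deg projection angle.
#' @slot spoke_index index of the originating spoke (or NA).
#' @slot peak_mm located peak position in mm (NA when invalid).
#' @slot peak_intensity peak intensity, a.u. (NA when invalid).
#' @slot valid logical; FALSE for flat / all-zero profiles.
#' @export
setClass("CoilProfile",
  representation(
    profile = "numeric",
    positions_mm = "numeric",
    angle_deg = "numeric",
    spoke_index = "integer",
    peak_mm = "numeric",
    peak_intensity = "numeric",
    valid = "logical"
  )
)

#' Catheter motion trace
#'
#' Per spoke-pair in-plane catheter displacement (mm, mean-centred for the
#' filtered variants) and the micro-coil peak intensity used as a qualitative
#' out-of-plane ("Z intensity") surrogate.  One sample per two consecutive
#' spokes, i.e. a temporal resolution of two repetition times.
#'
#' @slot times_s sample times (one per spoke pair).
#' @slot x_mm displacement along x.
#' @slot y_mm displacement along y.
#' @slot z_intensity micro-coil peak intensity, a.u.
#' @slot valid logical per sample; invalid samples were interpolated.
#' @slot variant one of `"raw"`, `"filtered"`, `"respiratory"`, `"cardiac"`.
#' @slot tr_s repetition time (sample spacing is `2 * tr_s`).
#' @export
setClass("MotionTrace",
  representation(
    times_s = "numeric",
    x_mm = "numeric",
    y_mm = "numeric",
    z_intensity = "numeric",
    valid = "logical",
    variant = "character",
    tr_s = "numeric"
  )
)

setValidity("MotionTrace", function(object) {
  n <- length(object@times_s)
  msg <- character()
  if (length(object@x_mm) != n || length(object@y_mm) != n || length(object@z_intensity) != n)
    msg <- c(msg, "x, y and z_intensity must have one sample per spoke pair")
  if (!object@variant %in% c("raw", "filtered", "respiratory", "cardiac"))
    msg <- c(msg, "unknown variant")
  if (length(msg)) msg else TRUE
})

#' Channel conditioning model
#'
#' Noise covariance across imaging channels, the corresponding pre-whitening
#' transform and the PCA compression matrix retaining a given fraction of the
#' whitened signal variance.
#'
#' @slot covariance complex noise covariance matrix across imaging channels.
#' @slot whitening whitening transform (applied as `x %*% whitening`).
#' @slot compression PCA compression matrix (applied after whitening).
#' @slot retained_variance fraction of variance kept by the compression.
#' @slot n_in,n_out channel counts before and after compression.
#' @export
setClass("ChannelModel",
  representation(
    covariance = "matrix",
    whitening = "matrix",
    compression = "matrix",
    retained_variance = "numeric",
    n_in = "integer",
    n_out = "integer"
  )
)

#' Motion-state multibaseline library
#'
#' Complex baseline images reconstructed per motion-state bin from
#' motion-corrected learning-phase spokes, together with the bin definitions,
#' per-bin spoke counts and the learning-span spoke indices.  Images are
#' stored per compressed imaging channel.
#'
#' @slot images complex array `N x N x n_bins x n_channels`.
#' @slot bins list describing the binning (scheme, levels, etc.).
#' @slot counts integer spokes-per-bin.
#' @slot labels integer bin label of every learning spoke.
#' @slot learning_idx indices of the learning spokes in the parent acquisition.
#' @slot matrix_size working image matrix size.
#' @export
setClass("BaselineLibrary",
  representation(
    images = "array",
    bins = "list",
    counts = "integer",
    labels = "integer",
    learning_idx = "integer",
    matrix_size = "integer"
  )
)

setValidity("BaselineLibrary", function(object) {
  msg <- character()
  d <- dim(object@images)
  if (length(d) != 4L) msg <- c(msg, "images must be N x N x n_bins x n_channels")
  else if (d[3] != length(object@counts)) msg <- c(msg, "one count per bin required")
  if (length(object@labels) != length(object@learning_idx))
    msg <- c(msg, "one bin label per learning spoke required")
  if (length(msg)) msg else TRUE
})

#' Orthonormalised 2D polynomial basis
#'
#' Monomials `x^p y^q` with `p + q <= order` over normalised `[-1, 1]^2`
#' image coordinates, orthonormalised over a mask; used as the smooth
#' "referenceless" background-phase basis absorbing B0 drift.
#'
#' @slot basis matrix, one column per basis function (rows = image voxels in
#'   column-major order), orthonormal over the mask rows.
#' @slot order maximal total polynomial order.
#' @slot mask logical matrix marking the voxels the basis is orthonormal over.
#' @slot matrix_size image matrix size.
#' @export
setClass("PolynomialBasis",
  representation(
    basis = "matrix",
    order = "integer",
    mask = "matrix",
    matrix_size = "integer"
  )
)

#' Configuration of the direct k-space temperature fit
#'
#' @slot lambda_sparsity l1 weight on the temperature phase map.
#' @slot beta_roughness weight of the second-order finite-difference spatial
#'   roughness penalty.
#' @slot window_spokes spokes per temperature frame.
#' @slot stride_spokes frame advance in spokes (defaults to the window).
#' @slot max_outer maximal number of outer alternation iterations.
#' @slot tol convergence tolerance on the maximal change of theta (radians).
#' @slot inner_theta proximal-gradient steps on theta per outer iteration.
#' @slot theta_sign_constraint constrain theta so heating is non-negative
#'   under the PRF sign convention.
#' @export
setClass("FitConfig",
  representation(
    lambda_sparsity = "numeric",
    beta_roughness = "numeric",
    window_spokes = "integer",
    stride_spokes = "integer",
    max_outer = "integer",
    tol = "numeric",
    inner_theta = "integer",
    theta_sign_constraint = "logical"
  )
)

setValidity("FitConfig", function(object) {
  msg <- character()
  if (object@lambda_sparsity < 0 || object@beta_roughness < 0)
    msg <- c(msg, "lambda and beta must be non-negative")
  if (object@window_spokes < 1L || object@stride_spokes < 1L)
    msg <- c(msg, "window and stride must be at least 1")
  if (length(msg)) msg else TRUE
})

#' Temperature map series
#'
#' Per-frame temperature-induced phase maps (radians) and temperature change
#' maps (degrees C), with frame timing, the contributing spoke indices and the
#' fitted baseline weights and polynomial coefficients.
#'
#' @slot theta array `N x N x n_frames`, phase in radians.
#' @slot deltaT array `N x N x n_frames`, temperature change in degrees C.
#' @slot times_s frame centre times.
#' @slot spoke_idx list of contributing spoke indices per frame.
#' @slot w baseline-weight matrix, `n_bins x n_frames`.
#' @slot c polynomial-coefficient matrix, `n_basis x n_frames`.
#' @slot converged logical per frame.
#' @slot window_spokes,stride_spokes frame windowing actually used.
#' @slot params acquisition parameters (for the PRF conversion).
#' @export
setClass("TemperatureSeries",
  representation(
    theta = "array",
    deltaT = "array",
    times_s = "numeric",
    spoke_idx = "list",
    w = "matrix",
    c = "matrix",
    converged = "logical",
    window_spokes = "integer",
    stride_spokes = "integer",
    params = "AcquisitionParams"
  )
)

#' Background-ROI temperature uncertainty
#'
#' Per-voxel temporal standard deviation of the temperature over the span
#' after library training and before heating, summarised over an unheated
#' region of interest as mean +/- SD (the paper-style uncertainty metric).
#'
#' @slot roi logical mask of the ROI.
#' @slot per_voxel_sd temporal SD of each ROI voxel, degrees C.
#' @slot mean_sd,sd_sd mean and SD of `per_voxel_sd`.
#' @slot n_frames number of frames in the evaluation span.
#' @export
setClass("RoiStats",
  representation(
    roi = "matrix",
    per_voxel_sd = "numeric",
    mean_sd = "numeric",
    sd_sd = "numeric",
    n_frames = "integer"
  )
)
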