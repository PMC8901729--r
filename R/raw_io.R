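#' @include AllClasses.R
NULL

#' Golden-angle increment in degrees
#'
#' `180 / phi` with `phi` the golden ratio; approximately 111.246 degrees,
#' i.e. 111.25 degrees at two decimals.
#' @export
GOLDEN_ANGLE_DEG <- 180 / ((1 + sqrt(5)) / 2)

#' Construct acquisition parameters
#'
#' Defaults reproduce the radial golden-angle gradient-echo protocol used for
#' catheter-tracked ablation monitoring at 1.5 T: 220 mm FoV, 512 readout
#' points with 2x oversampling (native matrix 256), TE 20 ms, TR 24.14 ms,
#' 250 Hz/px readout bandwidth.  The PRF coefficient defaults to the
#' conventional -0.01 ppm/degC.
#'
#' @param fov_mm field of view, mm.
#' @param n_readout acquired samples per spoke (even).
#' @param oversampling readout oversampling factor.
#' @param matrix_size native image matrix; defaults to
#'   `n_readout / oversampling`.
#' @param slice_thickness_mm slice thickness, mm.
#' @param te_s,tr_s echo and repetition time, seconds.
#' @param flip_deg flip angle, degrees.
#' @param readout_bandwidth_hz_per_px readout bandwidth, Hz per pixel.
#' @param b0_tesla static field, tesla.
#' @param gamma_hz_per_tesla gyromagnetic ratio, Hz per tesla.
#' @param prf_alpha_ppm_per_degC PRF thermal coefficient, ppm per degC.
#' @return an [AcquisitionParams-class] object.
#' @examples
#' acquisitionParams()
#' acquisitionParams(n_readout = 256L, fov_mm = 220)  # desk-scale matrix 128
#' @export
acquisitionParams <- function(fov_mm = 220, n_readout = 512L, oversampling = 2,
                              matrix_size = NULL, slice_thickness_mm = 3,
                              te_s = 0.020, tr_s = 0.02414, flip_deg = 15,
                              readout_bandwidth_hz_per_px = 250,
                              b0_tesla = 1.5, gamma_hz_per_tesla = 42.577e6,
                              prf_alpha_ppm_per_degC = -0.01) {
  n_readout <- as.integer(n_readout)
  if (is.null(matrix_size)) matrix_size <- as.integer(round(n_readout / oversampling))
  matrix_size <- as.integer(matrix_size)
  new("AcquisitionParams",
      fov_mm = fov_mm, n_readout = n_readout, oversampling = oversampling,
      matrix_size = matrix_size,
      k_spacing_cyc_fov = matrix_size / n_readout,
      slice_thickness_mm = slice_thickness_mm, te_s = te_s, tr_s = tr_s,
      flip_deg = flip_deg,
      readout_bandwidth_hz_per_px = readout_bandwidth_hz_per_px,
      b0_tesla = b0_tesla, gamma_hz_per_tesla = gamma_hz_per_tesla,
      prf_alpha_ppm_per_degC = prf_alpha_ppm_per_degC)
}

#' Golden-angle spoke sequence
#'
#' Accumulated golden-angle values `m * 180 / phi` degrees for spokes
#' `m = 0 .. n_spokes - 1`.  Values are not reduced modulo 360; callers reduce
#' when sampling.  Consecutive spokes differ by 111.25 degrees (2 d.p.).
#'
#' @param n_spokes number of spokes (>= 1).
#' @param start_index index of the first spoke (default 0), for simulating a
#'   late segment of a longer acquisition.
#' @return numeric vector of accumulated angles in degrees.
#' @examples
#' goldenAngles(3)                 # 0, 111.246..., 222.49...
#' diff(goldenAngles(2))           # the golden-angle increment
#' @export
goldenAngles <- function(n_spokes, start_index = 0L) {
  stopifnot(n_spokes >= 1)
  (start_index + seq_len(n_spokes) - 1) * GOLDEN_ANGLE_DEG
}

#' Pixel centre coordinates of the image grid
#'
#' @param n matrix size.
#' @param fov_mm field of view, mm.
#' @return coordinates in mm of the `n` pixel centres, centred on the FoV
#'   (pixel `n/2 + 1` sits at 0 mm, matching the DFT centring convention).
#' @keywords internal
pixelCoords <- function(n, fov_mm) {
  (seq_len(n) - 1 - n / 2) * fov_mm / n
}

#' Build the radial trajectory for a set of spokes
#'
#' Sample `i` of every spoke sits at radial coordinate
#' `kr[i] = (i - 1 - n_readout/2) * dk` cycles per FoV, with
#' `dk = matrix_size / n_readout` fixed at acquisition (and preserved under
#' readout truncation); the 2D location is `kr * (cos(rho), sin(rho))`.
#' With 512 samples and matrix 256 (2x oversampling) the edge sample
#' approaches half the matrix size in cycles per FoV.
#'
#' @param angles_deg per-spoke angles in degrees (accumulated golden angle).
#' @param params an [AcquisitionParams-class].
#' @param matrix_size target matrix for reconstruction; defaults to
#'   `params@matrix_size`.
#' @return a [Trajectory-class].
#' @export
buildTrajectory <- function(angles_deg, params, matrix_size = params@matrix_size) {
  n <- params@n_readout
  dk <- params@k_spacing_cyc_fov
  kr <- (seq_len(n) - 1 - n / 2) * dk
  new("Trajectory", kr = kr, angles_deg = as.numeric(angles_deg),
      fov_mm = params@fov_mm, matrix_size = as.integer(matrix_size))
}

paramsToList <- function(p) {
  list(fov_mm = p@fov_mm, n_readout = p@n_readout, oversampling = p@oversampling,
       matrix_size = p@matrix_size, k_spacing_cyc_fov = p@k_spacing_cyc_fov,
       slice_thickness_mm = p@slice_thickness_mm, te_s = p@te_s, tr_s = p@tr_s,
       flip_deg = p@flip_deg,
       readout_bandwidth_hz_per_px = p@readout_bandwidth_hz_per_px,
       b0_tesla = p@b0_tesla, gamma_hz_per_tesla = p@gamma_hz_per_tesla,
       prf_alpha_ppm_per_degC = p@prf_alpha_ppm_per_degC)
}

paramsFromList <- function(lst) {
  required <- c("fov_mm", "n_readout", "te_s", "tr_s")
  missing <- setdiff(required, names(lst))
  if (length(missing))
    stop("raw container is missing required acquisition field(s): ",
         paste(missing, collapse = ", "))
  p <- acquisitionParams(
    fov_mm = lst$fov_mm, n_readout = as.integer(lst$n_readout),
    oversampling = lst$oversampling %||% 2,
    matrix_size = lst$matrix_size,
    slice_thickness_mm = lst$slice_thickness_mm %||% 3,
    te_s = lst$te_s, tr_s = lst$tr_s, flip_deg = lst$flip_deg %||% 15,
    readout_bandwidth_hz_per_px = lst$readout_bandwidth_hz_per_px %||% 250,
    b0_tesla = lst$b0_tesla %||% 1.5,
    gamma_hz_per_tesla = lst$gamma_hz_per_tesla %||% 42.577e6,
    prf_alpha_ppm_per_degC = lst$prf_alpha_ppm_per_degC %||% -0.01)
  if (!is.null(lst$k_spacing_cyc_fov))
    p@k_spacing_cyc_fov <- lst$k_spacing_cyc_fov
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a raw radial k-space container
#'
#' @param data complex array `n_spokes x n_readout x n_channels`.
#' @param angles_deg accumulated golden angles per spoke.
#' @param times_s per-spoke timestamps, seconds.
#' @param channel_roles per-channel role flags.
#' @param params an [AcquisitionParams-class].
#' @return a [RadialKspace-class].
#' @export
radialKspace <- function(data, angles_deg, times_s, channel_roles, params) {
  new("RadialKspace", data = data, angles_deg = as.numeric(angles_deg),
      times_s = as.numeric(times_s), channel_roles = channel_roles,
      params = params)
}

#' Write / read raw radial acquisitions
#'
#' The native container is a single-file R serialisation holding the groups
#' `kspace`, `angles`, `times`, `roles`, `params` (plus `ground_truth` when a
#' simulated scene is attached).  When the `rhdf5` package is installed the
#' same layout can be written to / read from an HDF5 file (`format = "hdf5"`,
#' datasets `/kspace_real`, `/kspace_imag`, `/angles`, `/times`, `/roles` and
#' attributes under `/params`), which interoperates with ISMRMRD-style
#' converters for radial data.
#'
#' @param k a [RadialKspace-class].
#' @param path file path.
#' @param format `"rds"` (native, default) or `"hdf5"` (requires `rhdf5`).
#' @param ground_truth optional list stored alongside (e.g. simulation truth).
#' @return `readRaw()` returns the [RadialKspace-class]; any stored ground
#'   truth is attached as attribute `"ground_truth"`.
#' @export
writeRaw <- function(k, path, format = c("rds", "hdf5"), ground_truth = NULL) {
  format <- match.arg(format)
  stopifnot(is(k, "RadialKspace"))
  if (format == "rds") {
    payload <- list(container = "radialtherm-raw", version = 1L,
                    kspace = k@data, angles = k@angles_deg, times = k@times_s,
                    roles = k@channel_roles, params = paramsToList(k@params),
                    ground_truth = ground_truth)
    saveRDS(payload, path)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("format = 'hdf5' requires the rhdf5 package")
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(Re(k@data), path, "kspace_real")
    rhdf5::h5write(Im(k@data), path, "kspace_imag")
    rhdf5::h5write(k@angles_deg, path, "angles")
    rhdf5::h5write(k@times_s, path, "times")
    rhdf5::h5write(k@channel_roles, path, "roles")
    rhdf5::h5createGroup(path, "params")
    p <- paramsToList(k@params)
    for (nm in names(p)) rhdf5::h5write(p[[nm]], path, paste0("params/", nm))
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' @rdname writeRaw
#' @export
readRaw <- function(path, format = c("auto", "rds", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "rds"
  }
  if (format == "rds") {
    payload <- readRDS(path)
    if (!identical(payload$container, "radialtherm-raw"))
      stop("not a radialtherm raw container: ", path)
    if (is.null(payload$roles))
      stop("raw container is missing channel-role metadata; channels: ",
           paste(seq_len(dim(payload$kspace)[3]), collapse = ", "))
    k <- radialKspace(payload$kspace, payload$angles, payload$times,
                      payload$roles, paramsFromList(payload$params))
    if (!is.null(payload$ground_truth))
      attr(k, "ground_truth") <- payload$ground_truth
    k
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("format = 'hdf5' requires the rhdf5 package")
    ls <- rhdf5::h5ls(path)
    if (!"roles" %in% ls$name)
      stop("raw container is missing channel-role metadata; datasets present: ",
           paste(ls$name, collapse = ", "))
    dat <- rhdf5::h5read(path, "kspace_real") +
      1i * rhdf5::h5read(path, "kspace_imag")
    p <- rhdf5::h5read(path, "params")
    rhdf5::h5closeAll()
    radialKspace(dat, as.numeric(rhdf5::h5read(path, "angles")),
                 as.numeric(rhdf5::h5read(path, "times")),
                 as.character(rhdf5::h5read(path, "roles")),
                 paramsFromList(lapply(p, as.vector)))
  }
}

#' Subset spokes of a raw container
#'
#' @param k a [RadialKspace-class].
#' @param idx spoke indices to keep (increasing).
#' @return a [RadialKspace-class] with the selected spokes.
#' @export
subsetSpokes <- function(k, idx) {
  idx <- sort(unique(as.integer(idx)))
  radialKspace(k@data[idx, , , drop = FALSE], k@angles_deg[idx],
               k@times_s[idx], k@channel_roles, k@params)
}
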