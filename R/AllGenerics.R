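#' @include AllClasses.R
NULL

#' Accessors for raw radial k-space
#'
#' @param object a [RadialKspace-class] object.
#' @return `kspaceData()` the complex data array, `spokeAngles()` the
#'   accumulated golden-angle vector, `spokeTimes()` the timestamps,
#'   `channelRoles()` the per-channel role flags, `acqParams()` the
#'   [AcquisitionParams-class], `imagingChannels()` / `microcoilChannels()`
#'   the corresponding channel indices, `nSpokes()` the spoke count.
#' @name radialkspace-accessors
NULL

#' @rdname radialkspace-accessors
#' @export
setGeneric("kspaceData", function(object) standardGeneric("kspaceData"))
#' @rdname radialkspace-accessors
#' @export
setGeneric("spokeAngles", function(object) standardGeneric("spokeAngles"))
#' @rdname radialkspace-accessors
#' @export
setGeneric("spokeTimes", function(object) standardGeneric("spokeTimes"))
#' @rdname radialkspace-accessors
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))
#' @rdname radialkspace-accessors
#' @export
setGeneric("acqParams", function(object) standardGeneric("acqParams"))
#' @rdname radialkspace-accessors
#' @export
setGeneric("imagingChannels", function(object) standardGeneric("imagingChannels"))
#' @rdname radialkspace-accessors
#' @export
setGeneric("microcoilChannels", function(object) standardGeneric("microcoilChannels"))
#' @rdname radialkspace-accessors
#' @export
setGeneric("nSpokes", function(object) standardGeneric("nSpokes"))

#' @rdname radialkspace-accessors
setMethod("kspaceData", "RadialKspace", function(object) object@data)
#' @rdname radialkspace-accessors
setMethod("spokeAngles", "RadialKspace", function(object) object@angles_deg)
#' @rdname radialkspace-accessors
setMethod("spokeTimes", "RadialKspace", function(object) object@times_s)
#' @rdname radialkspace-accessors
setMethod("channelRoles", "RadialKspace", function(object) object@channel_roles)
#' @rdname radialkspace-accessors
setMethod("acqParams", "RadialKspace", function(object) object@params)
#' @rdname radialkspace-accessors
setMethod("imagingChannels", "RadialKspace", function(object) which(object@channel_roles == "imaging"))
#' @rdname radialkspace-accessors
setMethod("microcoilChannels", "RadialKspace",
          function(object) which(object@channel_roles != "imaging"))
#' @rdname radialkspace-accessors
setMethod("nSpokes", "RadialKspace", function(object) dim(object@data)[1L])

#' Temperature map extraction
#'
#' @param object a [TemperatureSeries-class].
#' @param frame frame index.
#' @return `temperatureMap()` one temperature-change map (degrees C);
#'   `frameTimes()` the frame centre times.
#' @export
setGeneric("temperatureMap", function(object, frame) standardGeneric("temperatureMap"))
#' @rdname temperatureMap
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname temperatureMap
setMethod("temperatureMap", "TemperatureSeries", function(object, frame) {
  object@deltaT[, , frame]
})
#' @rdname temperatureMap
setMethod("frameTimes", "TemperatureSeries", function(object) object@times_s)

#' Library accessors
#'
#' @param object a [BaselineLibrary-class].
#' @return `libraryImages()` the complex image array
#'   (`N x N x n_bins x n_channels`), `binCounts()` the spokes per bin.
#' @export
setGeneric("libraryImages", function(object) standardGeneric("libraryImages"))
#' @rdname libraryImages
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @rdname libraryImages
setMethod("libraryImages", "BaselineLibrary", function(object) object@images)
#' @rdname libraryImages
setMethod("binCounts", "BaselineLibrary", function(object) object@counts)

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams: FoV", object@fov_mm, "mm,",
      object@n_readout, "readout samples (oversampling", object@oversampling, "),",
      "matrix", object@matrix_size, "\n")
  cat("  TE", object@te_s * 1e3, "ms, TR", object@tr_s * 1e3, "ms, B0",
      object@b0_tesla, "T, alpha", object@prf_alpha_ppm_per_degC, "ppm/degC\n")
})

setMethod("show", "RadialKspace", function(object) {
  d <- dim(object@data)
  cat("RadialKspace:", d[1], "spokes x", d[2], "samples x", d[3], "channels\n")
  cat("  channel roles:", paste(object@channel_roles, collapse = ", "), "\n")
  cat("  time span:", round(min(object@times_s), 3), "-",
      round(max(object@times_s), 3), "s\n")
})

setMethod("show", "PhantomScene", function(object) {
  cat("PhantomScene:", object@n_pix, "x", object@n_pix, "px, FoV",
      object@fov_mm, "mm,", dim(object@sensitivities)[3], "imaging channels\n")
  cat("  motion:", object@motion_model$kind,
      "| hotspot peak", object@hotspot_model$peak_degC, "degC\n")
})

setMethod("show", "MotionTrace", function(object) {
  cat("MotionTrace (", object@variant, "): ", length(object@times_s),
      " samples at ", round(2 * object@tr_s * 1e3, 2), " ms\n", sep = "")
})

setMethod("show", "BaselineLibrary", function(object) {
  d <- dim(object@images)
  cat("BaselineLibrary:", d[3], "bins at matrix", d[1], "x", d[2],
      "(", d[4], "channel(s) )\n")
  cat("  spokes per bin:", paste(range(object@counts), collapse = "-"), "\n")
})

setMethod("show", "TemperatureSeries", function(object) {
  d <- dim(object@theta)
  cat("TemperatureSeries:", d[3], "frames at matrix", d[1], "x", d[2], "\n")
  cat("  window", object@window_spokes, "spokes, stride", object@stride_spokes,
      "-> frame spacing", round(object@stride_spokes * object@params@tr_s, 4), "s\n")
})

setMethod("show", "RoiStats", function(object) {
  cat("RoiStats:", sum(object@roi), "voxels,", object@n_frames, "frames;",
      "temperature uncertainty", round(object@mean_sd, 2), "+/-",
      round(object@sd_sd, 2), "degC\n")
})
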